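# Exclusion filtering of EHLA pairs with a per-rule audit. Rules evaluate in
# a fixed order; a pair failing several rules is attributed to the first.
#
# Note on half-life: the published exclusion table lists "Half-life > 1 h" in
# its exclusion column, which would discard every stable peptide. That
# contradicts the biology and the accompanying stepwise-filtering text, so
# this module RETAINS pairs with half-life > 1 h and excludes those at or
# below 1 h. The threshold and every rule are configurable.

#' Default exclusion rule sets
#'
#' Class-I rules (in order): toxicity = Toxin; half-life <= 1 h; instability
#' index > 40; allergenicity = Probable Allergen; ID = 0. Class-II rules:
#' the first four, then IFN-gamma = Negative, immunogenicity < 50,
#' antigenicity < 0.4. Boundary values (exactly 1 h, 40, 50, 0.4) are
#' retained, matching the strict printed inequalities.
#'
#' @param mhc_class `"I"` or `"II"`.
#' @return A data.frame with columns `rule`, `column`, `op`, `threshold`,
#'   `enabled`; `op` is one of `eq` (exclude on equality with `threshold`),
#'   `gt`/`lt`/`le` (exclude when the value compares that way).
#' @export
default_filter_rules <- function(mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  shared <- data.frame(
    rule = c("toxicity", "half_life", "instability_index", "allergenicity"),
    column = c("toxicity_label", "half_life_hours", "instability_index",
               "allergenicity_label"),
    op = c("eq", "le", "gt", "eq"),
    threshold = c("Toxin", "1", "40", "Probable Allergen"),
    enabled = TRUE,
    stringsAsFactors = FALSE
  )
  extra <- if (mhc_class == "I") {
    data.frame(rule = "id", column = "id_label", op = "eq", threshold = "0",
               enabled = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(
      rule = c("ifng", "immunogenicity", "antigenicity"),
      column = c("ifng_label", "immunogenicity", "antigenicity"),
      op = c("eq", "lt", "lt"),
      threshold = c("Negative", "50", "0.4"),
      enabled = TRUE,
      stringsAsFactors = FALSE
    )
  }
  rbind(shared, extra)
}

# Logical vector: does each pair trip this exclusion rule?
.rule_trips <- function(pairs, rule) {
  if (!rule$column %in% names(pairs)) {
    stop("filter rule '", rule$rule, "' requires missing feature column '",
         rule$column, "'", call. = FALSE)
  }
  v <- pairs[[rule$column]]
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    stop("pair ", bad, " (epitope ", pairs$mutant_sequence[bad], ", allele ",
         pairs$allele[bad], ") is missing feature '", rule$column, "'",
         call. = FALSE)
  }
  switch(rule$op,
    eq = v == rule$threshold,
    gt = as.numeric(v) > as.numeric(rule$threshold),
    lt = as.numeric(v) < as.numeric(rule$threshold),
    le = as.numeric(v) <= as.numeric(rule$threshold),
    stop("unknown filter op '", rule$op, "'", call. = FALSE)
  )
}

#' Apply exclusion rules to EHLA pairs
#'
#' Evaluates the rules in order; each pair is kept iff it trips no enabled
#' rule, and a rejected pair is attributed to the first rule it trips.
#'
#' @param pairs Feature-populated pair data.frame.
#' @param rules Rule data.frame ([default_filter_rules()] or an override).
#' @return List with `kept` (surviving pairs) and `audit` (data.frame of
#'   per-rule rejection counts plus an attribute-free summary row order:
#'   one row per rule, columns `rule`, `rejected`; `sum(rejected)` plus
#'   `nrow(kept)` equals the input count).
#' @export
apply_filters <- function(pairs, rules) {
  rules <- rules[rules$enabled, , drop = FALSE]
  n <- nrow(pairs)
  rejected_by <- rep(NA_character_, n)
  for (i in seq_len(nrow(rules))) {
    trips <- if (n) .rule_trips(pairs, rules[i, ]) else logical(0)
    newly <- is.na(rejected_by) & trips
    rejected_by[newly] <- rules$rule[i]
  }
  audit <- data.frame(
    rule = rules$rule,
    rejected = vapply(rules$rule,
                      function(r) sum(rejected_by == r, na.rm = TRUE),
                      integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  kept <- pairs[is.na(rejected_by), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, audit = audit)
}

#' Filter EHLA-I pairs by the class-I exclusion criteria
#'
#' @param pairs Class-I pair data.frame carrying `toxicity_label`,
#'   `half_life_hours`, `instability_index`, `allergenicity_label`,
#'   `id_label`.
#' @param rules Optional rule override (see [default_filter_rules()]).
#' @return List with `kept` and `audit` (see [apply_filters()]).
#' @export
filter_ehla_i <- function(pairs, rules = default_filter_rules("I")) {
  apply_filters(pairs, rules)
}

#' Filter EHLA-II pairs by the class-II exclusion criteria
#'
#' @param pairs Class-II pair data.frame carrying `toxicity_label`,
#'   `half_life_hours`, `instability_index`, `allergenicity_label`,
#'   `ifng_label`, `immunogenicity`, `antigenicity`.
#' @param rules Optional rule override.
#' @return List with `kept` and `audit`.
#' @export
filter_ehla_ii <- function(pairs, rules = default_filter_rules("II")) {
  apply_filters(pairs, rules)
}

#' Read filter-rule overrides from YAML
#'
#' The YAML maps rule names to `threshold` and/or `enabled` entries, e.g.
#' `instability_index: {threshold: 45}` or `half_life: {enabled: false}`.
#'
#' @param path YAML file path.
#' @param mhc_class `"I"` or `"II"`.
#' @return A rule data.frame with overrides applied.
#' @export
filter_rules_from_yaml <- function(path, mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  rules <- default_filter_rules(mhc_class)
  cfg <- yaml::read_yaml(path)
  for (nm in names(cfg)) {
    i <- match(nm, rules$rule)
    if (is.na(i)) stop("unknown filter rule in YAML: '", nm, "'",
                       call. = FALSE)
    if (!is.null(cfg[[nm]]$threshold)) {
      rules$threshold[i] <- as.character(cfg[[nm]]$threshold)
    }
    if (!is.null(cfg[[nm]]$enabled)) {
      rules$enabled[i] <- isTRUE(cfg[[nm]]$enabled)
    }
  }
  rules
}
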