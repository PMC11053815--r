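# Pluggable predictor registry. External binding/immunogenicity/safety tools
# are never re-implemented here: each feature has a named slot that can be
# bound to (a) a deterministic seeded mock, (b) a bring-your-own-scores CSV of
# pre-computed values, or (c) a local calculator (hydropathicity, ACC
# antigenicity, ProtParam-style descriptors).

#' Feature catalogue
#'
#' The features the pipeline knows about, their value kind, the direction in
#' which values are favourable, and the MHC class they apply to.
#'
#' @return A data.frame with columns `name`, `kind` (`real`/`categorical`),
#'   `direction` (`lower`/`higher`/`none`), `classes` (`I`, `II` or `both`).
#' @export
feature_catalog <- function() {
  data.frame(
    name = c("mhcflurry_rank", "netmhcpan_rank", "binding_affinity_nM",
             "stability_halflife", "wt_mut_rank_ratio", "immunogenicity",
             "antigenicity", "hydropathicity", "toxicity_label",
             "allergenicity_label", "ifng_label", "netmhcii_rank",
             "netmhcii_affinity", "half_life_hours", "instability_index",
             "isoelectric_point", "aliphatic_index", "gravy"),
    kind = c("real", "real", "real", "real", "real", "real", "real", "real",
             "categorical", "categorical", "categorical", "real", "real",
             "real", "real", "real", "real", "real"),
    direction = c("lower", "lower", "lower", "higher", "higher", "higher",
                  "higher", "none", "none", "none", "none", "lower", "lower",
                  "higher", "lower", "none", "none", "none"),
    classes = c("I", "I", "I", "I", "I", "both", "both", "both", "both",
                "both", "II", "II", "II", "both", "both", "both", "both",
                "both"),
    stringsAsFactors = FALSE
  )
}

#' Default feature set per MHC class
#'
#' The features collected for every pair of a class before modelling and
#' filtering.
#'
#' @param mhc_class `"I"` or `"II"`.
#' @return Character vector of feature names.
#' @export
default_features <- function(mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  if (mhc_class == "I") {
    c("mhcflurry_rank", "netmhcpan_rank", "stability_halflife",
      "wt_mut_rank_ratio", "immunogenicity", "antigenicity", "hydropathicity",
      "toxicity_label", "allergenicity_label", "half_life_hours",
      "instability_index")
  } else {
    c("netmhcii_rank", "netmhcii_affinity", "immunogenicity", "antigenicity",
      "hydropathicity", "toxicity_label", "allergenicity_label", "ifng_label",
      "half_life_hours", "instability_index", "isoelectric_point",
      "aliphatic_index", "gravy")
  }
}

#' Wild-type to mutant binding-rank ratio
#'
#' Percentile rank of the matched wild-type window divided by the rank of the
#' mutant window on the same allele; values above 1 mean the mutation
#' improved predicted binding.
#'
#' @param wt_rank,mut_rank Positive percentile ranks.
#' @return `wt_rank / mut_rank` (vectorised).
#' @export
rank_ratio <- function(wt_rank, mut_rank) {
  if (any(mut_rank == 0)) {
    stop("mutant rank of 0: rank ratio undefined", call. = FALSE)
  }
  if (any(wt_rank <= 0) || any(mut_rank < 0)) {
    stop("percentile ranks must be positive", call. = FALSE)
  }
  wt_rank / mut_rank
}

#' Auto-cross-covariance antigenicity features
#'
#' Transforms a peptide into a fixed-length vector of auto- and
#' cross-covariances of its Hellberg z-scale descriptor series: after
#' centering each descriptor series over the sequence, term `(j, k, l)` is
#' `sum_i a_j(i) * a_k(i + l) / (n - l)` for lags `l = 1..lag`. The flattened
#' order is lag-major, then descriptor `j`, then descriptor `k`
#' (`z1z1_l1, z1z2_l1, ..., z3z3_l1, z1z1_l2, ...`).
#'
#' @param seq Peptide string with `|seq| > lag`.
#' @param lag Maximum lag (default 1, suited to short epitopes).
#' @return Named numeric vector of length `9 * lag`.
#' @export
acc_antigenicity_features <- function(seq, lag = 1L) {
  chars <- .check_peptide(seq)
  n <- length(chars)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1", call. = FALSE)
  if (lag >= n) {
    stop("lag (", lag, ") must be smaller than the sequence length (", n, ")",
         call. = FALSE)
  }
  z <- zscales()[chars, , drop = FALSE]
  a <- sweep(z, 2L, colMeans(z))  # centered descriptor series
  out <- numeric(0)
  for (l in seq_len(lag)) {
    for (j in 1:3) {
      for (k in 1:3) {
        i <- seq_len(n - l)
        v <- sum(a[i, j] * a[i + l, k]) / (n - l)
        out <- c(out, stats::setNames(v, sprintf("z%dz%d_l%d", j, k, l)))
      }
    }
  }
  out
}

#' Scalar ACC antigenicity score
#'
#' Combines the ACC feature vector into one antigenicity value through a
#' linear model. The default weights are a fixed package asset chosen to give
#' scores on a VaxiJen-like 0-1-ish scale; they make no claim to reproduce
#' any external tool's model and are fully replaceable.
#'
#' @param seq Peptide string.
#' @param lag Maximum lag passed to [acc_antigenicity_features()].
#' @param weights List with elements `intercept` (scalar) and `coef`
#'   (numeric vector of length `9 * lag`); `NULL` uses the package default.
#' @return Numeric scalar.
#' @export
antigenicity_score <- function(seq, lag = 1L, weights = NULL) {
  feats <- acc_antigenicity_features(seq, lag)
  if (is.null(weights)) weights <- default_antigenicity_weights(lag)
  if (length(weights$coef) != length(feats)) {
    stop("antigenicity weights have length ", length(weights$coef),
         " but ", length(feats), " ACC features were computed", call. = FALSE)
  }
  weights$intercept + sum(weights$coef * feats)
}

#' Default ACC antigenicity weights
#'
#' Auto-covariance terms (j == k) carry weight 0.06 and cross terms 0.015,
#' scaled by 1/lag, with intercept 0.45 - arbitrary but fixed, placing
#' typical peptides near the conventional 0.4 antigenicity threshold.
#'
#' @param lag Maximum lag.
#' @return List with `intercept` and `coef`.
#' @export
default_antigenicity_weights <- function(lag = 1L) {
  per_lag <- c(0.06, 0.015, 0.015,
               0.015, 0.06, 0.015,
               0.015, 0.015, 0.06)
  list(intercept = 0.45, coef = rep(per_lag / lag, times = lag))
}

# --- deterministic mock predictors -----------------------------------------

# 32-bit FNV-1a over a string, in double arithmetic safe for R.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), b)
    h <- (h %/% 65536) * 65536 + lo
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# Deterministic uniform draw in (0, 1] from hashed inputs.
.mock_uniform <- function(epitope, allele, feature, seed) {
  (.fnv1a(paste(epitope, allele, feature, seed, sep = "|")) + 1) / 4294967296
}

#' Deterministic mock predictor for one feature
#'
#' Returns a predictor function `(epitope, allele) -> value` whose output is
#' a pure hash of (epitope sequence, allele name, feature name, seed), mapped
#' into the feature's plausible range: percentile ranks in `(0, 100]`,
#' stability in `(0, 12]` hours, affinities log-uniform in `(0.1, 50000]` nM,
#' scores in `(0, 100]` or `(0, 1.2]`, and categorical labels from a seeded
#' Bernoulli. Identical inputs always give identical outputs.
#'
#' @param feature Feature name from [feature_catalog()].
#' @param seed Integer seed mixed into the hash.
#' @return A function `(epitope, allele) -> value`.
#' @export
mock_predictor <- function(feature, seed = 0L) {
  force(feature); force(seed)
  function(epitope, allele) {
    u <- .mock_uniform(epitope, allele, feature, seed)
    switch(feature,
      mhcflurry_rank = ,
      netmhcpan_rank = ,
      netmhcii_rank = u * 100,
      binding_affinity_nM = ,
      netmhcii_affinity = exp(log(0.1) + u * (log(50000) - log(0.1))),
      stability_halflife = u * 12,
      immunogenicity = u * 100,
      antigenicity = u * 1.2,
      toxicity_label = if (u < 0.10) "Toxin" else "Non-Toxin",
      allergenicity_label =
        if (u < 0.30) "Probable Allergen" else "Probable Non-Allergen",
      ifng_label = if (u < 0.35) "Negative" else "Positive",
      stop("no mock defined for feature '", feature, "'", call. = FALSE)
    )
  }
}

#' Build a predictor registry
#'
#' A registry is a named list of predictor functions
#' `(epitope, allele) -> value`, one per feature. By default the locally
#' computable descriptors (hydropathicity, ACC antigenicity, instability
#' index, half-life, isoelectric point, aliphatic index, GRAVY) are bound to
#' the package's own calculators and every external-tool feature to its
#' seeded mock; `overrides` replaces any slot, e.g. with [csv_registry()]
#' entries holding real pre-computed scores.
#'
#' @param seed Seed for the mock predictors.
#' @param overrides Named list of predictor functions taking precedence.
#' @param local_antigenicity If `TRUE` (default) antigenicity is the local
#'   ACC score; otherwise the seeded mock.
#' @return Named list of predictor functions.
#' @export
build_registry <- function(seed = 0L, overrides = list(),
                           local_antigenicity = TRUE) {
  reg <- list(
    hydropathicity = function(epitope, allele) hydropathicity(epitope),
    half_life_hours = function(epitope, allele) half_life_nend(epitope),
    instability_index = function(epitope, allele) instability_index(epitope),
    isoelectric_point = function(epitope, allele) isoelectric_point(epitope),
    aliphatic_index = function(epitope, allele) aliphatic_index(epitope),
    gravy = function(epitope, allele) gravy(epitope)
  )
  reg$antigenicity <- if (local_antigenicity) {
    function(epitope, allele) antigenicity_score(epitope)
  } else {
    mock_predictor("antigenicity", seed)
  }
  for (f in c("mhcflurry_rank", "netmhcpan_rank", "binding_affinity_nM",
              "stability_halflife", "immunogenicity", "toxicity_label",
              "allergenicity_label", "ifng_label", "netmhcii_rank",
              "netmhcii_affinity")) {
    reg[[f]] <- mock_predictor(f, seed)
  }
  for (nm in names(overrides)) reg[[nm]] <- overrides[[nm]]
  reg
}

#' Registry entries from a pre-computed feature CSV
#'
#' Reads a bring-your-own-scores table with the strict header
#' `epitope,allele,feature,value` and returns lookup predictors, one per
#' feature present. Unknown feature names are rejected; querying an
#' (epitope, allele) combination absent from the table is an error.
#'
#' @param path CSV path.
#' @return Named list of predictor functions, suitable for the `overrides`
#'   argument of [build_registry()].
#' @export
csv_registry <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), c("epitope", "allele", "feature", "value"))) {
    stop("feature CSV must have exactly the header ",
         "'epitope,allele,feature,value'", call. = FALSE)
  }
  unknown <- setdiff(unique(tab$feature), feature_catalog()$name)
  if (length(unknown)) {
    stop("unknown feature name(s) in CSV: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cat_kind <- stats::setNames(feature_catalog()$kind, feature_catalog()$name)
  out <- list()
  for (f in unique(tab$feature)) {
    sub <- tab[tab$feature == f, , drop = FALSE]
    key <- paste(sub$epitope, sub$allele, sep = "|")
    if (anyDuplicated(key)) {
      stop("duplicate (epitope, allele) rows for feature '", f, "'",
           call. = FALSE)
    }
    vals <- stats::setNames(sub$value, key)
    if (cat_kind[[f]] == "real") vals <- stats::setNames(as.numeric(vals), key)
    out[[f]] <- local({
      vals_f <- vals; f_name <- f
      function(epitope, allele) {
        k <- paste(epitope, allele, sep = "|")
        if (!k %in% names(vals_f)) {
          stop("no pre-computed '", f_name, "' value for epitope ", epitope,
               " on allele ", allele, call. = FALSE)
        }
        unname(vals_f[[k]])
      }
    })
  }
  out
}

#' Populate EHLA pair feature columns
#'
#' Evaluates every demanded feature for every pair and appends the values as
#' columns. `wt_mut_rank_ratio` is derived, not predicted: the registry's
#' `mhcflurry_rank` predictor is evaluated on the matched wild-type window
#' and divided by the mutant window's rank. Demanding a feature with no
#' registry binding, or one inapplicable to the pairs' MHC class, is a
#' configuration error naming the feature.
#'
#' @param pairs EHLA pair data.frame from [make_ehla_pairs()].
#' @param registry Named list of predictors from [build_registry()].
#' @param features Character vector of demanded feature names; defaults to
#'   [default_features()] for the pairs' class.
#' @return `pairs` with one extra column per demanded feature.
#' @export
collect_features <- function(pairs, registry, features = NULL) {
  if (!nrow(pairs)) return(pairs)
  cls <- unique(pairs$mhc_class)
  if (length(cls) != 1L) {
    stop("pairs must share a single MHC class", call. = FALSE)
  }
  if (is.null(features)) features <- default_features(cls)
  cat_tab <- feature_catalog()
  for (f in features) {
    row <- cat_tab[cat_tab$name == f, , drop = FALSE]
    if (nrow(row) && !row$classes %in% c("both", cls)) {
      stop("feature '", f, "' applies to class ", row$classes,
           " pairs only, not class ", cls, call. = FALSE)
    }
    if (f == "wt_mut_rank_ratio") {
      if (is.null(registry$mhcflurry_rank)) {
        stop("feature 'wt_mut_rank_ratio' demands an 'mhcflurry_rank' ",
             "predictor in the registry", call. = FALSE)
      }
      wt <- mapply(registry$mhcflurry_rank,
                   pairs$wildtype_sequence, pairs$allele)
      mut <- mapply(registry$mhcflurry_rank,
                    pairs$mutant_sequence, pairs$allele)
      pairs[[f]] <- rank_ratio(as.numeric(wt), as.numeric(mut))
    } else {
      if (is.null(registry[[f]])) {
        stop("no predictor bound for demanded feature '", f, "'",
             call. = FALSE)
      }
      vals <- mapply(registry[[f]], pairs$mutant_sequence, pairs$allele,
                     SIMPLIFY = FALSE)
      pairs[[f]] <- unname(unlist(vals))
    }
  }
  pairs
}
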