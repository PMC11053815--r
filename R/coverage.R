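# Projected population coverage of an EHLA set under a Hardy-Weinberg diploid
# genotype model, per locus, combined across loci by convolution; plus the
# minimal set-cover optimiser that finds the fewest pairs preserving the
# covered-allele set (hence the coverage).

#' Validate an allele frequency table
#'
#' @param tab Data.frame with columns `region`, `locus`, `allele`,
#'   `frequency`. Frequencies are taken as given: a per-locus sum below 1
#'   leaves residual mass for unlisted alleles, which cover nothing.
#' @return The validated data.frame.
#' @export
allele_frequency_table <- function(tab) {
  need <- c("region", "locus", "allele", "frequency")
  if (!all(need %in% names(tab))) {
    stop("allele frequency table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!nrow(tab)) stop("allele frequency table is empty", call. = FALSE)
  if (any(tab$frequency < 0)) {
    stop("negative allele frequency", call. = FALSE)
  }
  sums <- tapply(tab$frequency, paste(tab$region, tab$locus), sum)
  if (any(sums > 1 + 1e-9)) {
    stop("allele frequencies sum to > 1 within locus: ",
         paste(names(sums)[sums > 1 + 1e-9], collapse = ", "), call. = FALSE)
  }
  tab
}

#' Read an allele frequency CSV
#'
#' @param path CSV with header `region,locus,allele,frequency`; lines
#'   starting with `#` are treated as comments.
#' @return Validated frequency data.frame.
#' @export
read_allele_frequencies <- function(path) {
  allele_frequency_table(utils::read.csv(path, stringsAsFactors = FALSE,
                                         comment.char = "#"))
}

# Per-locus hit pmf by diploid genotype enumeration under HWE. `p` is the
# named frequency vector, `hits` the per-allele pair counts (same names).
# Presence-based counting: a homozygote scores its allele's pairs once.
.locus_pmf <- function(p, hits) {
  resid <- max(0, 1 - sum(p))
  pp <- c(p, .residual = resid)
  hh <- c(hits, .residual = 0)
  k <- length(pp)
  maxh <- 2L * max(hh)
  pmf <- numeric(maxh + 1L)
  for (i in seq_len(k)) {
    for (j in i:k) {
      prob <- if (i == j) pp[i]^2 else 2 * pp[i] * pp[j]
      h <- if (i == j) hh[i] else hh[i] + hh[j]
      pmf[h + 1L] <- pmf[h + 1L] + prob
    }
  }
  pmf
}

.convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Hit-count distribution of an EHLA set in a population
#'
#' For one region, per HLA locus, enumerates unordered diploid genotypes
#' under Hardy-Weinberg equilibrium (frequency `p_i * p_j`, doubled
#' off-diagonal; the residual mass of unlisted alleles covers nothing). An
#' individual's hit count is the number of (epitope, allele) pairs whose
#' allele appears in the genotype - presence-based, so homozygotes do not
#' double-count. Per-locus distributions are combined across loci by
#' convolution (locus independence). Pairs whose allele is not typed in the
#' region's table are excluded and reported. DRB1/3/4/5 pairs pool into one
#' DR locus.
#'
#' @param pairs EHLA pair data.frame with `allele` and `locus` columns.
#' @param freqs Frequency table ([allele_frequency_table()]).
#' @param region Region name present in `freqs`.
#' @param dosage If `TRUE`, count homozygous hits twice instead
#'   (dosage-based); default `FALSE`.
#' @return A list of class `hit_distribution`: `pmf` (probability over hit
#'   counts `0..H`), `region`, `n_pairs_used`, `excluded` (pairs dropped for
#'   untyped alleles).
#' @export
hit_distribution <- function(pairs, freqs, region, dosage = FALSE) {
  freqs <- allele_frequency_table(freqs)
  ftab <- freqs[freqs$region == region, , drop = FALSE]
  if (!nrow(ftab)) stop("unknown region: '", region, "'", call. = FALSE)

  typed <- pairs$allele %in% ftab$allele
  excluded <- pairs[!typed, , drop = FALSE]
  used <- pairs[typed, , drop = FALSE]

  pmf <- 1  # point mass at 0 hits
  for (loc in unique(ftab$locus)) {
    sub <- ftab[ftab$locus == loc, , drop = FALSE]
    p <- stats::setNames(sub$frequency, sub$allele)
    counts <- table(used$allele[used$allele %in% sub$allele])
    hits <- stats::setNames(integer(length(p)), names(p))
    hits[names(counts)] <- as.integer(counts)
    lp <- if (dosage) .locus_pmf_dosage(p, hits) else .locus_pmf(p, hits)
    pmf <- .convolve_pmf(pmf, lp)
  }
  # trim trailing zero mass
  last <- max(which(pmf > 0), 1L)
  pmf <- pmf[seq_len(last)]
  structure(list(pmf = pmf, region = region, n_pairs_used = nrow(used),
                 excluded = excluded),
            class = "hit_distribution")
}

# Dosage-based variant: homozygote counts its allele's pairs twice.
.locus_pmf_dosage <- function(p, hits) {
  resid <- max(0, 1 - sum(p))
  pp <- c(p, .residual = resid)
  hh <- c(hits, .residual = 0)
  k <- length(pp)
  pmf <- numeric(2L * max(hh) + 1L)
  for (i in seq_len(k)) {
    for (j in i:k) {
      prob <- if (i == j) pp[i]^2 else 2 * pp[i] * pp[j]
      h <- hh[i] + hh[j]
      pmf[h + 1L] <- pmf[h + 1L] + prob
    }
  }
  pmf
}

#' @export
print.hit_distribution <- function(x, ...) {
  cat("<hit_distribution>", x$region, "-", x$n_pairs_used, "pairs, max",
      length(x$pmf) - 1L, "hits\n")
  invisible(x)
}

#' Coverage, average hit and PC90 of a hit distribution
#'
#' Coverage is the probability of at least one hit; average hit the expected
#' hit count; PC90 the hit count carried by at least 90% of the population,
#' interpolated piecewise-linearly on the complementary CDF
#' `S(h) = P(hits >= h)`: with `k` the integer satisfying
#' `S(k) >= 0.9 > S(k+1)`, `PC90 = k + (S(k) - 0.9) / (S(k) - S(k+1))`.
#' A zero-coverage distribution has PC90 defined as 0.
#'
#' @param d A `hit_distribution`.
#' @return A list of class `coverage_report`: `coverage`, `average_hit`,
#'   `pc90`, `region`.
#' @export
coverage_metrics <- function(d) {
  pmf <- d$pmf
  h <- seq_along(pmf) - 1L
  coverage <- 1 - pmf[1]
  average <- sum(h * pmf)
  # S[k+1] = P(hits >= k), k = 0..H; beyond H it is 0
  S <- rev(cumsum(rev(pmf)))
  S_at <- function(k) if (k + 1L <= length(S)) S[k + 1L] else 0
  if (coverage <= 0) {
    pc90 <- 0
  } else {
    k <- max(which(S >= 0.9)) - 1L  # S(0) = 1 guarantees existence
    pc90 <- k + (S_at(k) - 0.9) / (S_at(k) - S_at(k + 1L))
  }
  structure(list(coverage = coverage, average_hit = average, pc90 = pc90,
                 region = d$region),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %s: coverage %.2f%%, average hit %.2f, PC90 %.2f\n",
              x$region, 100 * x$coverage, x$average_hit, x$pc90))
  invisible(x)
}

#' Coverage summary across regions
#'
#' One coverage report per requested region plus an unweighted arithmetic
#' mean of the regional coverages. A region named `"World"` contributes its
#' own row but is excluded from the regional average (the world figure comes
#' from the world frequency entry, never from averaging).
#'
#' @param pairs EHLA pair data.frame.
#' @param freqs Frequency table.
#' @param regions Character vector of region names; default: all in `freqs`.
#' @return A list with `per_region` (data.frame `region`, `coverage`,
#'   `average_hit`, `pc90`, `n_pairs_used`) and `average_regional_coverage`.
#' @export
regional_summary <- function(pairs, freqs, regions = NULL) {
  freqs <- allele_frequency_table(freqs)
  if (is.null(regions)) regions <- unique(freqs$region)
  reports <- lapply(regions, function(r) {
    d <- hit_distribution(pairs, freqs, r)
    c(coverage_metrics(d), list(n = d$n_pairs_used))
  })
  per <- data.frame(
    region = regions,
    coverage = vapply(reports, `[[`, numeric(1), "coverage"),
    average_hit = vapply(reports, `[[`, numeric(1), "average_hit"),
    pc90 = vapply(reports, `[[`, numeric(1), "pc90"),
    n_pairs_used = vapply(reports, `[[`, numeric(1), "n"),
    stringsAsFactors = FALSE
  )
  regional <- per$coverage[per$region != "World"]
  list(per_region = per,
       average_regional_coverage =
         if (length(regional)) mean(regional) else NA_real_)
}

# --- minimal set cover -----------------------------------------------------

#' Minimal set cover
#'
#' Smallest sub-collection of `sets` whose union equals the union of all
#' sets. Greedy (most new elements first; ties by higher `score`, then by
#' `label` ascending) followed by redundancy pruning; when the universe has
#' at most `exact_limit` elements an exact branch-and-bound solver replaces
#' the greedy answer.
#'
#' @param sets List of character vectors.
#' @param scores Optional numeric tie-break scores (higher preferred).
#' @param labels Optional character tie-break labels (lexicographic).
#' @param exact_limit Universe size up to which the exact solver runs
#'   (default 20).
#' @return Integer indices into `sets` of the chosen sub-collection.
#' @export
min_set_cover <- function(sets, scores = NULL, labels = NULL,
                          exact_limit = 20L) {
  n <- length(sets)
  if (!n) return(integer(0))
  if (is.null(scores)) scores <- rep(0, n)
  if (is.null(labels)) labels <- sprintf("%09d", seq_len(n))
  universe <- sort(unique(unlist(sets)))
  if (!length(universe)) return(integer(0))

  # deterministic candidate order: score desc, label asc
  cand_order <- order(-scores, labels)

  greedy <- integer(0)
  uncovered <- universe
  while (length(uncovered)) {
    gains <- vapply(sets, function(s) length(intersect(s, uncovered)),
                    integer(1))
    if (max(gains) == 0L) break  # unreachable: universe is the union
    best <- cand_order[gains[cand_order] == max(gains)][1]
    greedy <- c(greedy, best)
    uncovered <- setdiff(uncovered, sets[[best]])
  }
  # redundancy pruning, revisiting picks in reverse selection order
  for (i in rev(seq_along(greedy))) {
    others <- greedy[-i]
    if (all(sets[[greedy[i]]] %in% unlist(sets[others]))) {
      greedy <- others
    }
  }

  if (length(universe) > exact_limit) return(sort(greedy))

  # exact branch-and-bound on element -> covering-set structure
  best_sol <- greedy
  covers <- lapply(universe, function(el) {
    which(vapply(sets, function(s) el %in% s, logical(1)))
  })
  names(covers) <- universe
  recurse <- function(chosen, uncovered) {
    if (!length(uncovered)) {
      if (length(chosen) < length(best_sol)) best_sol <<- chosen
      return(invisible(NULL))
    }
    if (length(chosen) + 1L > length(best_sol)) return(invisible(NULL))
    # branch on the uncovered element with fewest covering sets
    ncov <- vapply(uncovered, function(el) length(covers[[el]]), integer(1))
    el <- uncovered[which.min(ncov)]
    cands <- covers[[el]]
    cands <- cands[order(-scores[cands], labels[cands])]
    for (s in cands) {
      recurse(c(chosen, s), setdiff(uncovered, sets[[s]]))
    }
    invisible(NULL)
  }
  recurse(integer(0), universe)
  sort(best_sol)
}

#' Minimal EHLA pair set preserving population coverage
#'
#' Each pair covers its single allele, so the optimiser returns the smallest
#' subset of pairs whose covered-allele set equals that of the full input -
#' which guarantees an identical hit-versus-none coverage in every region.
#' Pairs whose allele is untyped in the region's frequency table are set
#' aside first (they cannot affect coverage there). Among pairs of the same
#' allele the deterministic tie-break prefers the higher `score`, then the
#' lexicographically smaller (epitope, allele).
#'
#' @param pairs EHLA pair data.frame (optionally with a `score` column).
#' @param freqs Frequency table.
#' @param region Region whose typed-allele universe defines coverage.
#' @return The chosen subset of `pairs` rows.
#' @export
optimize_minimal_set <- function(pairs, freqs, region) {
  if (!nrow(pairs)) return(pairs)
  freqs <- allele_frequency_table(freqs)
  ftab <- freqs[freqs$region == region, , drop = FALSE]
  if (!nrow(ftab)) stop("unknown region: '", region, "'", call. = FALSE)
  typed <- pairs$allele %in% ftab$allele
  used <- pairs[typed, , drop = FALSE]
  if (!nrow(used)) return(used)
  sets <- as.list(used$allele)
  scores <- if ("score" %in% names(used)) used$score else rep(0, nrow(used))
  labels <- paste(used$mutant_sequence, used$allele)
  idx <- min_set_cover(sets, scores = scores, labels = labels)
  out <- used[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stepwise filter-coverage audit
#'
#' Applies exclusion rules cumulatively in order, recomputing coverage after
#' each step, and flags the first rule (if any) whose application reduces
#' the region's coverage.
#'
#' @param pairs Feature-populated pair data.frame.
#' @param freqs Frequency table.
#' @param rules Rule data.frame (see [default_filter_rules()]).
#' @param region Region name.
#' @return Data.frame with one row per step (step 0 = unfiltered): `step`,
#'   `rule`, `n_pairs`, `coverage`, `average_hit`, `pc90`,
#'   `coverage_reduced`.
#' @export
stepwise_filter_coverage <- function(pairs, freqs, rules, region) {
  rules <- rules[rules$enabled, , drop = FALSE]
  steps <- list()
  current <- pairs
  add_row <- function(step, rule, df, prev_cov) {
    m <- coverage_metrics(hit_distribution(df, freqs, region))
    data.frame(step = step, rule = rule, n_pairs = nrow(df),
               coverage = m$coverage, average_hit = m$average_hit,
               pc90 = m$pc90,
               coverage_reduced = !is.na(prev_cov) & m$coverage < prev_cov,
               stringsAsFactors = FALSE)
  }
  steps[[1]] <- add_row(0L, "(none)", current, NA_real_)
  for (i in seq_len(nrow(rules))) {
    prev_cov <- steps[[length(steps)]]$coverage
    current <- apply_filters(current, rules[i, , drop = FALSE])$kept
    steps[[length(steps) + 1L]] <- add_row(i, rules$rule[i], current,
                                           prev_cov)
  }
  do.call(rbind, steps)
}
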