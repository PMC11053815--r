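# Independent brute-force oracles and small fixture builders shared across
# test files. These deliberately re-derive quantities by the most naive route
# available so they stay independent of the implementation they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# Naive positional Kyte-Doolittle sum over 1-based positions [4, n-1].
oracle_hydropathicity <- function(seq, kd) {
  chars <- strsplit(seq, "")[[1]]
  total <- 0
  for (i in seq_along(chars)) {
    if (i >= 4 && i <= length(chars) - 1) total <- total + kd[[chars[i]]]
  }
  total
}

# Naive DIWV dipeptide sum.
oracle_instability <- function(seq, diwv) {
  chars <- strsplit(seq, "")[[1]]
  s <- 0
  for (i in seq_len(length(chars) - 1)) s <- s + diwv[chars[i], chars[i + 1]]
  10 / length(chars) * s
}

# Aliphatic index from first principles.
oracle_aliphatic <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  x <- function(r) mean(chars == r)
  100 * x("A") + 2.9 * 100 * x("V") + 3.9 * 100 * (x("I") + x("L"))
}

# Zero of the net-charge curve by dense grid scan + linear interpolation.
oracle_pi_grid <- function(seq, step = 5e-4) {
  ph <- seq(0, 14, by = step)
  q <- epivax::peptide_charge(seq, ph)
  i <- which(q <= 0)[1]  # charge decreases in pH
  ph[i - 1] + step * q[i - 1] / (q[i - 1] - q[i])
}

# Counting-based confusion metrics.
oracle_metrics <- function(pred, truth) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
  }
  list(accuracy = (tp + tn) / length(pred),
       ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       tpr = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

# Mann-Whitney AUC with mid-rank tie handling.
oracle_auc_mw <- function(score, truth) {
  r <- rank(score)  # mid-ranks for ties
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Brute-force window enumeration: all (start, length) windows containing the
# mutated position and fully inside the protein.
oracle_windows <- function(prot_len, pos, lengths) {
  out <- list()
  for (L in sort(lengths)) {
    for (s in seq_len(prot_len)) {
      if (s + L - 1 <= prot_len && s <= pos && pos <= s + L - 1) {
        out[[length(out) + 1]] <- c(start = s, length = L)
      }
    }
  }
  out
}

# Closed-form per-mutation candidate count.
oracle_window_count <- function(prot_len, pos, lengths) {
  sum(vapply(lengths, function(L) {
    max(0L, min(pos, prot_len - L + 1L) - max(1L, pos - L + 1L) + 1L)
  }, integer(1)))
}

# Full joint diploid genotype enumeration across loci: returns the hit pmf
# as a named numeric vector over 0..max hits. `loci` is a list, one element
# per locus, each a list(freq = named vector, hits = named integer vector).
oracle_hit_pmf <- function(loci) {
  per_locus <- lapply(loci, function(lc) {
    p <- c(lc$freq, .other = max(0, 1 - sum(lc$freq)))
    h <- c(lc$hits, .other = 0L)
    combos <- list()
    for (i in seq_along(p)) {
      for (j in i:length(p)) {
        prob <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
        hit <- if (i == j) h[i] else h[i] + h[j]
        combos[[length(combos) + 1]] <- c(prob = unname(prob),
                                          hits = unname(hit))
      }
    }
    combos
  })
  # outer product over loci (positional indexing: prob first, hits second)
  acc <- list(c(1, 0))
  for (combos in per_locus) {
    nxt <- list()
    for (a in acc) {
      for (b in combos) {
        nxt[[length(nxt) + 1]] <- c(a[[1]] * b[[1]], a[[2]] + b[[2]])
      }
    }
    acc <- nxt
  }
  hmax <- max(vapply(acc, function(x) x[[2]], numeric(1)))
  pmf <- numeric(hmax + 1)
  for (x in acc) pmf[x[[2]] + 1] <- pmf[x[[2]] + 1] + x[[1]]
  pmf
}

# Exhaustive minimum set cover over all subsets (n <= ~14).
oracle_min_cover_size <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  if (!length(universe)) return(0L)
  n <- length(sets)
  best <- n
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) >= best) next
    if (all(universe %in% unlist(sets[idx]))) best <- length(idx)
  }
  best
}

# A tiny EHLA-like pair data.frame on class-I alleles.
toy_pairs <- function(epitopes, alleles) {
  n <- length(epitopes)
  data.frame(
    mutation = rep("X1Y", n),
    mutant_sequence = epitopes,
    wildtype_sequence = epitopes,
    start = rep(1L, n), length = nchar(epitopes),
    mutation_offset = rep(1L, n),
    mhc_class = rep("I", n),
    allele = alleles,
    locus = substr(sub("^HLA-", "", alleles), 1, 1),
    stringsAsFactors = FALSE
  )
}

# Frequency table fixture: one region, one locus "A".
toy_freqs <- function(alleles, freqs, region = "World") {
  data.frame(region = region, locus = "A", allele = alleles,
             frequency = freqs, stringsAsFactors = FALSE)
}
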