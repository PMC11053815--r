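# Locally computed per-epitope physicochemical descriptors. All functions are
# pure; the constant tables they consume are the vendored CSVs in
# inst/extdata/constants (see constants.R).

#' Positional Kyte-Doolittle hydropathicity
#'
#' Sum of Kyte-Doolittle hydropathy values over positions 4 to n-1 of the
#' epitope (1-based, inclusive), where n is the epitope length. This windowed
#' sum deliberately drops the anchor-adjacent termini and is the descriptor
#' used by the classifier and filters, distinct from the GRAVY mean.
#'
#' @param seq Peptide string, length >= 5 so the range `[4, n-1]` is
#'   non-empty.
#' @return Numeric scalar.
#' @export
hydropathicity <- function(seq) {
  chars <- .check_peptide(seq)
  n <- length(chars)
  if (n < 5L) {
    stop("hydropathicity requires a peptide of length >= 5, got ", n,
         call. = FALSE)
  }
  sum(kd_scale()[chars[4:(n - 1L)]])
}

#' GRAVY score
#'
#' Grand average of hydropathy: arithmetic mean of Kyte-Doolittle values over
#' all residues.
#'
#' @param seq Peptide string.
#' @return Numeric scalar in `[-4.5, 4.5]`.
#' @export
gravy <- function(seq) {
  chars <- .check_peptide(seq)
  mean(kd_scale()[chars])
}

#' Instability index
#'
#' Guruprasad dipeptide-weight statistic as computed by ProtParam:
#' `(10 / L) * sum of DIWV(seq[i], seq[i+1])` over all adjacent residue
#' pairs. Values above 40 conventionally denote an unstable peptide.
#'
#' @param seq Peptide string, length >= 2.
#' @return Numeric scalar.
#' @export
instability_index <- function(seq) {
  chars <- .check_peptide(seq)
  L <- length(chars)
  if (L < 2L) stop("instability index requires length >= 2", call. = FALSE)
  m <- diwv_matrix()
  idx <- cbind(chars[-L], chars[-1L])
  (10 / L) * sum(m[idx])
}

#' Aliphatic index
#'
#' Ikai's relative volume occupied by aliphatic side chains:
#' `100*X(Ala) + 2.9*100*X(Val) + 3.9*100*(X(Ile) + X(Leu))` with X the mole
#' fractions.
#'
#' @param seq Peptide string.
#' @return Non-negative numeric scalar.
#' @export
aliphatic_index <- function(seq) {
  chars <- .check_peptide(seq)
  n <- length(chars)
  100 * (sum(chars == "A") + 2.9 * sum(chars == "V") +
           3.9 * (sum(chars == "I") + sum(chars == "L"))) / n
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch net charge over the free N- and C-termini plus the
#' ionizable side chains, using the Bjellqvist pKa set. Vectorised over `ph`.
#'
#' @param seq Peptide string.
#' @param ph pH value(s).
#' @return Numeric net charge, same length as `ph`.
#' @export
peptide_charge <- function(seq, ph) {
  chars <- .check_peptide(seq)
  pk <- pka_set()
  pos_frac <- function(pka) 1 / (1 + 10^(ph - pka))
  neg_frac <- function(pka) 1 / (1 + 10^(pka - ph))

  nt <- chars[1L]
  nt_pka <- if (nt %in% names(pk$nterm)) pk$nterm[[nt]] else pk$nterm_default
  ct <- chars[length(chars)]
  ct_pka <- if (ct %in% names(pk$cterm)) pk$cterm[[ct]] else pk$cterm_default

  charge <- pos_frac(nt_pka) - neg_frac(ct_pka)
  for (res in names(pk$side_pos)) {
    charge <- charge + sum(chars == res) * pos_frac(pk$side_pos[[res]])
  }
  for (res in names(pk$side_neg)) {
    charge <- charge - sum(chars == res) * neg_frac(pk$side_neg[[res]])
  }
  charge
}

#' Isoelectric point
#'
#' pH at which the peptide's net charge (termini plus ionizable side chains,
#' Bjellqvist pKa set) crosses zero, located by bisection on `(0, 14)` to a
#' tolerance of 1e-4.
#'
#' @param seq Peptide string.
#' @return pH in `(0, 14)`.
#' @export
isoelectric_point <- function(seq) {
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (peptide_charge(seq, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' N-end-rule half-life
#'
#' Predicted in vitro half-life in mammalian reticulocytes, a table lookup on
#' the N-terminal residue, returned in hours.
#'
#' @param seq Peptide string.
#' @return Half-life in hours.
#' @export
half_life_nend <- function(seq) {
  chars <- .check_peptide(seq)
  unname(nend_table()[chars[1L]])
}

#' All physicochemical descriptors for one peptide
#'
#' @param seq Peptide string (length >= 5).
#' @return Named list with `hydropathicity`, `gravy`, `half_life_hours`,
#'   `isoelectric_point`, `instability_index`, `aliphatic_index`.
#' @export
physchem_profile <- function(seq) {
  list(
    hydropathicity = hydropathicity(seq),
    gravy = gravy(seq),
    half_life_hours = half_life_nend(seq),
    isoelectric_point = isoelectric_point(seq),
    instability_index = instability_index(seq),
    aliphatic_index = aliphatic_index(seq)
  )
}
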