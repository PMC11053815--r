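# Epitope window enumeration and EHLA pair construction.
#
# Coordinates are 1-based closed intervals throughout, matching missense
# notation ("L858R" mutates residue 858); any 0-based arithmetic stays inside
# these functions.

#' Built-in HLA allele panels
#'
#' The default class-I (HLA-A/HLA-B) and class-II (DR/DQ/DP) allele panels
#' used when no panel is supplied: 27 class-I and 27 class-II alleles in
#' IEDB star-colon notation, with class-II alpha/beta heterodimers written as
#' single paired units.
#'
#' @param mhc_class `"I"` or `"II"`.
#' @return A data.frame with columns `allele`, `locus`, `mhc_class`.
#' @export
default_allele_panel <- function(mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  names <- if (mhc_class == "I") {
    c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*02:03", "HLA-A*02:06",
      "HLA-A*03:01", "HLA-A*11:01", "HLA-A*23:01", "HLA-A*24:02",
      "HLA-A*26:01", "HLA-A*30:01", "HLA-A*30:02", "HLA-A*31:01",
      "HLA-A*32:01", "HLA-A*33:01", "HLA-A*68:01", "HLA-A*68:02",
      "HLA-B*07:02", "HLA-B*08:01", "HLA-B*15:01", "HLA-B*35:01",
      "HLA-B*40:01", "HLA-B*44:02", "HLA-B*44:03", "HLA-B*51:01",
      "HLA-B*53:01", "HLA-B*57:01", "HLA-B*58:01")
  } else {
    c("HLA-DRB1*01:01", "HLA-DRB1*03:01", "HLA-DRB1*04:01", "HLA-DRB1*04:05",
      "HLA-DRB1*07:01", "HLA-DRB1*08:02", "HLA-DRB1*09:01", "HLA-DRB1*11:01",
      "HLA-DRB1*12:01", "HLA-DRB1*13:02", "HLA-DRB1*15:01", "HLA-DRB3*01:01",
      "HLA-DRB3*02:02", "HLA-DRB4*01:01", "HLA-DRB5*01:01",
      "HLA-DPA1*01:03/DPB1*02:01", "HLA-DPA1*01:03/DPB1*04:01",
      "HLA-DPA1*02:01/DPB1*01:01", "HLA-DPA1*02:01/DPB1*05:01",
      "HLA-DPA1*02:01/DPB1*14:01", "HLA-DPA1*03:01/DPB1*04:02",
      "HLA-DQA1*01:01/DQB1*05:01", "HLA-DQA1*01:02/DQB1*06:02",
      "HLA-DQA1*03:01/DQB1*03:02", "HLA-DQA1*04:01/DQB1*04:02",
      "HLA-DQA1*05:01/DQB1*02:01", "HLA-DQA1*05:01/DQB1*03:01")
  }
  hla_panel(names)
}

#' Build an HLA panel from allele names
#'
#' Parses locus and MHC class from IEDB star-colon names. Class-I loci are A
#' and B; class-II loci are DRB1/DRB3/DRB4/DRB5, DP and DQ (paired
#' alpha/beta names are one unit).
#'
#' @param names Character vector of allele names (e.g. `"HLA-A*02:01"`,
#'   `"HLA-DQA1*05:01/DQB1*02:01"`).
#' @return A data.frame with columns `allele`, `locus`, `mhc_class`.
#' @export
hla_panel <- function(names) {
  locus <- vapply(names, hla_locus, character(1), USE.NAMES = FALSE)
  cls <- ifelse(locus %in% c("A", "B"), "I", "II")
  data.frame(allele = names, locus = locus, mhc_class = cls,
             stringsAsFactors = FALSE)
}

hla_locus <- function(name) {
  stem <- sub("^HLA-", "", name)
  if (grepl("^A\\*", stem)) return("A")
  if (grepl("^B\\*", stem)) return("B")
  if (grepl("^DRB[1345]\\*", stem)) return(sub("\\*.*$", "", stem))
  if (grepl("^DPA", stem) || grepl("^DPB", stem)) return("DP")
  if (grepl("^DQA", stem) || grepl("^DQB", stem)) return("DQ")
  stop("cannot determine HLA locus for allele '", name, "'", call. = FALSE)
}

# Locus used for population-coverage grouping: DRB1/3/4/5 pool into DR.
coverage_locus <- function(locus) {
  ifelse(grepl("^DRB", locus), "DR", locus)
}

#' Enumerate mutant epitope windows around a missense mutation
#'
#' Returns every window of each requested length that lies fully inside the
#' protein and contains the mutated position, together with the matched
#' wild-type window. Windows are ordered by length then start.
#'
#' @param protein A `protein_record`.
#' @param mutation A `missense_mutation` (validated against the protein).
#' @param lengths Integer vector of window lengths; defaults to
#'   `c(9, 10)` for class I and `15` for class II.
#' @param mhc_class `"I"` or `"II"`.
#' @return A data.frame of epitope candidates with columns `mutation`,
#'   `mutant_sequence`, `wildtype_sequence`, `start`, `length`,
#'   `mutation_offset`, `mhc_class`. Zero rows if no window fits.
#' @export
enumerate_epitopes <- function(protein, mutation,
                               lengths = NULL,
                               mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  if (is.null(lengths)) lengths <- if (mhc_class == "I") c(9L, 10L) else 15L
  lengths <- as.integer(lengths)
  n <- nchar(protein$sequence)
  if (any(lengths < 1L) || any(lengths > n)) {
    stop("window lengths must be between 1 and the protein length (", n, ")",
         call. = FALSE)
  }
  mutated <- apply_mutation(protein, mutation)  # also validates wt residue
  pos <- mutation$pos

  out <- list()
  for (L in sort(lengths)) {
    starts <- seq.int(max(1L, pos - L + 1L), min(pos, n - L + 1L))
    starts <- starts[starts >= 1L & starts + L - 1L <= n]
    if (!length(starts)) next
    out[[length(out) + 1L]] <- data.frame(
      mutation = mutation$token,
      mutant_sequence = substring(mutated, starts, starts + L - 1L),
      wildtype_sequence = substring(protein$sequence, starts, starts + L - 1L),
      start = starts,
      length = L,
      mutation_offset = pos - starts + 1L,
      mhc_class = mhc_class,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(mutation = character(), mutant_sequence = character(),
                      wildtype_sequence = character(), start = integer(),
                      length = integer(), mutation_offset = integer(),
                      mhc_class = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate epitope candidates for a list of mutations
#'
#' @param protein A `protein_record`.
#' @param mutations List of `missense_mutation` objects.
#' @inheritParams enumerate_epitopes
#' @return Row-bound candidate data.frame (see [enumerate_epitopes()]).
#' @export
enumerate_all_epitopes <- function(protein, mutations, lengths = NULL,
                                   mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  parts <- lapply(mutations, enumerate_epitopes, protein = protein,
                  lengths = lengths, mhc_class = mhc_class)
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Cross epitope candidates with an HLA panel into EHLA pairs
#'
#' Produces the full cross product: every candidate paired with every allele,
#' with no deduplication (duplicate epitope sequences from different
#' mutations are retained deliberately).
#'
#' @param candidates Candidate data.frame from [enumerate_epitopes()].
#' @param panel Allele panel data.frame from [default_allele_panel()] or
#'   [hla_panel()]; must share the candidates' MHC class.
#' @return A data.frame with one row per (candidate, allele) pair: all
#'   candidate columns plus `allele` and `locus`.
#' @export
make_ehla_pairs <- function(candidates, panel) {
  if (nrow(candidates) && nrow(panel)) {
    cls <- unique(c(candidates$mhc_class, panel$mhc_class))
    if (length(cls) != 1L) {
      stop("candidates and panel must share a single MHC class; got: ",
           paste(cls, collapse = ", "), call. = FALSE)
    }
  }
  if (!nrow(candidates) || !nrow(panel)) {
    empty <- candidates[integer(0), , drop = FALSE]
    empty$allele <- character(0)
    empty$locus <- character(0)
    return(empty)
  }
  idx_c <- rep(seq_len(nrow(candidates)), each = nrow(panel))
  idx_p <- rep(seq_len(nrow(panel)), times = nrow(candidates))
  res <- candidates[idx_c, , drop = FALSE]
  res$allele <- panel$allele[idx_p]
  res$locus <- panel$locus[idx_p]
  rownames(res) <- NULL
  res
}
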