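#' Read a protein record from a FASTA file
#'
#' Reads exactly one amino-acid record. Files holding more than one record are
#' rejected so that a mutation list can never be silently validated against
#' the wrong isoform.
#'
#' @param path Path to a FASTA file containing a single protein record.
#' @return A list of class `protein_record` with elements `id` and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records", call. = FALSE)
  if (length(set) > 1L) {
    stop("FASTA file contains ", length(set),
         " records; exactly one protein record is required", call. = FALSE)
  }
  protein_record(id = names(set)[1], sequence = as.character(set[[1]]))
}

#' Construct a protein record
#'
#' @param id Record identifier.
#' @param sequence Amino-acid sequence, one-letter codes, 1-based positions.
#' @return A list of class `protein_record`.
#' @export
protein_record <- function(id, sequence) {
  .check_peptide(sequence, what = paste0("protein '", id, "'"))
  structure(list(id = as.character(id), sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, "-", nchar(x$sequence), "aa\n")
  invisible(x)
}

#' Parse a missense-mutation token
#'
#' Tokens use the conventional `<wt><position><mut>` form, e.g. `"L858R"`:
#' wild-type residue, 1-based position, mutant residue.
#'
#' @param token Character scalar.
#' @return A list of class `missense_mutation` with fields `wt`, `pos`, `mut`
#'   and the original `token`.
#' @export
parse_mutation <- function(token) {
  raw <- trimws(token)
  m <- regmatches(raw, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", raw))[[1]]
  if (length(m) != 4L) {
    stop("malformed mutation token: '", token,
         "' (expected e.g. 'L858R')", call. = FALSE)
  }
  wt <- toupper(m[2]); mut <- toupper(m[4])
  for (r in c(wt, mut)) {
    if (!r %in% AA_ALPHABET) {
      stop("non-canonical residue '", r, "' in mutation token '", token, "'",
           call. = FALSE)
    }
  }
  if (wt == mut) {
    stop("mutation token '", token,
         "' has identical wild-type and mutant residues", call. = FALSE)
  }
  pos <- as.integer(m[3])
  if (is.na(pos) || pos < 1L) {
    stop("invalid position in mutation token '", token, "'", call. = FALSE)
  }
  structure(list(wt = wt, pos = pos, mut = mut, token = raw),
            class = "missense_mutation")
}

#' Read a mutation list file
#'
#' Plain UTF-8 text, one token per line; blank lines and lines starting with
#' `#` are ignored.
#'
#' @param path Path to the mutation list.
#' @return List of `missense_mutation` objects.
#' @export
read_mutation_list <- function(path) {
  if (!file.exists(path)) stop("mutation list not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_mutation)
}

#' Apply a missense mutation to a protein
#'
#' Validates that the protein carries the stated wild-type residue at the
#' stated position before substituting; a mismatch signals a wrong sequence or
#' an off-by-one in the mutation list and aborts.
#'
#' @param protein A `protein_record`.
#' @param mutation A `missense_mutation`.
#' @return The mutated amino-acid string.
#' @export
apply_mutation <- function(protein, mutation) {
  seq <- protein$sequence
  n <- nchar(seq)
  if (mutation$pos > n) {
    stop("mutation ", mutation$token, " position ", mutation$pos,
         " exceeds protein length ", n, call. = FALSE)
  }
  found <- substr(seq, mutation$pos, mutation$pos)
  if (found != mutation$wt) {
    stop("wild-type mismatch for ", mutation$token, ": protein has '", found,
         "' at position ", mutation$pos, ", expected '", mutation$wt, "'",
         call. = FALSE)
  }
  paste0(substr(seq, 1L, mutation$pos - 1L), mutation$mut,
         substr(seq, mutation$pos + 1L, n))
}
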