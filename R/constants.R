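# Vendored physicochemical constant tables. Each loader reads its CSV from
# inst/extdata/constants once and caches the parsed form in a package-local
# environment; provenance is recorded in the CSV headers.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.const_cache <- new.env(parent = emptyenv())

.const_path <- function(file) {
  path <- system.file("extdata", "constants", file, package = "epivax")
  if (!nzchar(path)) {
    # devtools::load_all() fallback
    path <- file.path("inst", "extdata", "constants", file)
  }
  if (!file.exists(path)) {
    stop("constant table not found: ", file, call. = FALSE)
  }
  path
}

.read_const <- function(file) {
  utils::read.csv(.const_path(file), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector of per-residue hydropathy values over the 20 canonical
#' amino acids (one-letter codes).
#'
#' @return Named numeric vector of length 20.
#' @export
kd_scale <- function() {
  if (is.null(.const_cache$kd)) {
    tab <- .read_const("kyte_doolittle.csv")
    .const_cache$kd <- stats::setNames(tab$kd, tab$residue)
  }
  .const_cache$kd
}

# 20x20 dipeptide instability weight matrix (rows = first residue).
diwv_matrix <- function() {
  if (is.null(.const_cache$diwv)) {
    tab <- .read_const("diwv.csv")
    m <- matrix(NA_real_, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    m[cbind(tab$first, tab$second)] <- tab$weight
    stopifnot(!anyNA(m))
    .const_cache$diwv <- m
  }
  .const_cache$diwv
}

# N-end rule half-lives (hours, mammalian reticulocytes) keyed by the
# N-terminal residue.
nend_table <- function() {
  if (is.null(.const_cache$nend)) {
    tab <- .read_const("nend_halflife.csv")
    .const_cache$nend <- stats::setNames(tab$half_life_hours, tab$residue)
  }
  .const_cache$nend
}

# Bjellqvist pKa set as a list: side-chain pKas split by charge sign plus
# residue-specific terminal pKas with defaults.
pka_set <- function() {
  if (is.null(.const_cache$pka)) {
    tab <- .read_const("pka_bjellqvist.csv")
    side <- tab[tab$kind == "side", ]
    nt <- tab[tab$kind == "nterm", ]
    ct <- tab[tab$kind == "cterm", ]
    .const_cache$pka <- list(
      side_pos = stats::setNames(side$pka[side$charge == "positive"],
                                 side$group[side$charge == "positive"]),
      side_neg = stats::setNames(side$pka[side$charge == "negative"],
                                 side$group[side$charge == "negative"]),
      nterm_default = tab$pka[tab$kind == "nterm_default"],
      nterm = stats::setNames(nt$pka, nt$group),
      cterm_default = tab$pka[tab$kind == "cterm_default"],
      cterm = stats::setNames(ct$pka, ct$group)
    )
  }
  .const_cache$pka
}

# Hellberg three-component z-scale descriptors, one row per residue.
zscales <- function() {
  if (is.null(.const_cache$z)) {
    tab <- .read_const("zscales_hellberg.csv")
    m <- as.matrix(tab[, c("z1", "z2", "z3")])
    rownames(m) <- tab$residue
    .const_cache$z <- m
  }
  .const_cache$z
}

# Validate a peptide string: canonical alphabet only, non-empty.
.check_peptide <- function(seq, what = "peptide") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop(what, " contains non-canonical residue(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chars
}
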