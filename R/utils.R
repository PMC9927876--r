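#' Reverse-complement nucleotide sequences
#'
#' @param x character vector of sequences over `A`, `C`, `G`, `T`, `N`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

str_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences; names are the full
#'   record identifiers.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  out
}

#' Write sequences to FASTA
#'
#' Records are wrapped at 60 columns and identifiers written verbatim.
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

# Deterministic child seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}
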