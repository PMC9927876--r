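#' Genetic code registry
#'
#' Returns a translation table for one of the genetic codes used when
#' annotating virus genomes from microbial eukaryote cultures.  The
#' registry maps the short names to NCBI translation tables: `standard` is
#' table 1, `mito` is table 4 (mold/protozoan mitochondrial, in which `TGA`
#' encodes tryptophan rather than a stop), and `plastid` is table 11
#' (bacterial/archaeal/plant plastid).  Other NCBI tables can be requested
#' through `ncbi_id`, e.g. for taxa whose mitochondria use table 5.
#'
#' @param code_id one of `"standard"`, `"mito"`, `"plastid"`.
#' @param ncbi_id optional NCBI translation table identifier (character)
#'   overriding the default mapping for `code_id`.
#' @return a list with elements `code_id`, `ncbi_id`, `table` (named
#'   character vector over all 64 codons, stops as `"*"`), and `stops`
#'   (character vector of stop codons).
#' @examples
#' gc <- genetic_code("mito")
#' gc$table[["TGA"]]  # "W"
#' @export
genetic_code <- function(code_id = c("standard", "mito", "plastid"),
                         ncbi_id = NULL) {
  code_id <- match.arg(code_id)
  if (is.null(ncbi_id)) {
    ncbi_id <- switch(code_id, standard = "1", mito = "4", plastid = "11")
  }
  tab <- Biostrings::getGeneticCode(as.character(ncbi_id))
  names(tab) <- gsub("U", "T", names(tab))
  stopifnot(length(tab) == 64)
  list(code_id = code_id,
       ncbi_id = as.character(ncbi_id),
       table = tab,
       stops = names(tab)[tab == "*"])
}

#' Translate a nucleotide sequence
#'
#' Translates codon by codon under the supplied genetic code.  Stop codons
#' become `"*"`.  Codons containing `N` (or any symbol outside `ACGT`)
#' translate to `"X"`; a codon that could be a stop given its `N`s is still
#' treated as non-stop, which is the conservative choice when handling
#' partial genome assemblies.
#'
#' @param seq nucleotide string; length must be divisible by 3.
#' @param code a genetic code from [genetic_code()].
#' @return amino-acid string, one symbol per codon.
#' @export
translate_seq <- function(seq, code = genetic_code("standard")) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(code$table[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
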