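#' BLOSUM62 substitution matrix with neutral unknowns
#'
#' The standard BLOSUM62 matrix (as distributed with Biostrings) with the
#' `X` row and column set to 0, so that unknown residues are neutral: any
#' symbol outside the matrix alphabet is remapped to `X` by the aligner and
#' scores 0 against everything.  The `*` (stop) symbol keeps its usual -4
#' penalty, which lets translated-frame queries containing stops still
#' anchor local alignments on either side.
#'
#' @return integer matrix with single-character dimnames.
#' @export
blosum62_matrix <- function() {
  if (!is.null(.align_cache$blosum62)) return(.align_cache$blosum62)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  .align_cache$blosum62 <- m
  m
}

.align_cache <- new.env(parent = emptyenv())

#' Nucleotide scoring matrix
#'
#' Match/mismatch scheme over `ACGTN`; `N` scores 0 against everything.
#'
#' @param match,mismatch scores (defaults +5/-4).
#' @return integer matrix with dimnames.
#' @export
nt_matrix <- function(match = 5L, mismatch = -4L) {
  a <- c("A", "C", "G", "T", "N")
  m <- matrix(as.integer(mismatch), 5, 5, dimnames = list(a, a))
  diag(m) <- as.integer(match)
  m["N", ] <- 0L
  m[, "N"] <- 0L
  storage.mode(m) <- "integer"
  m
}

#' Karlin-Altschul-style parameters
#'
#' Fixed calibration constants used to turn raw local-alignment scores into
#' bit scores and E-values.  The protein values are the gapped constants
#' commonly used with BLOSUM62 and gap penalties 11/1; the nucleotide
#' values correspond to a simple match/mismatch scheme.  These are a
#' calibration approximation: no per-search parameter fitting is performed.
#'
#' @return list with `lambda` and `K`.
#' @export
aa_karlin_params <- function() list(lambda = 0.267, K = 0.041)

#' @rdname aa_karlin_params
#' @export
nt_karlin_params <- function() list(lambda = 0.192, K = 0.176)

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment of two sequences under an affine gap model where
#' a gap of total length \eqn{k} costs `gap_open + k * gap_extend`.
#' Percent identity is computed over aligned columns with gap columns
#' counted in the denominator.  Residues absent from the matrix alphabet
#' are treated as `X` (score 0 against anything).
#'
#' @param a,b sequences (query, target).
#' @param matrix substitution matrix (default [blosum62_matrix()]).
#' @param gap_open,gap_extend affine gap penalties; `gap_open >= gap_extend > 0`.
#' @return list with `raw_score`, `q_aln`, `t_aln` (gapped strings),
#'   `pct_identity`, `aln_len`, `n_id`, `n_mismatch`, `n_gap`,
#'   `n_gapopen`, and 0-based half-open `query_span` and `target_span`.
#'   A raw score of 0 yields an empty alignment.
#' @export
local_align <- function(a, b, matrix = blosum62_matrix(),
                        gap_open = 11L, gap_extend = 1L) {
  stopifnot(nchar(a) > 0, nchar(b) > 0, gap_open >= gap_extend,
            gap_extend > 0)
  r <- c_sw_align(a, b, matrix, as.integer(gap_open), as.integer(gap_extend))
  list(raw_score = r$score, q_aln = r$q_aln, t_aln = r$t_aln,
       pct_identity = r$pct_identity, aln_len = r$aln_len,
       n_id = r$n_id, n_mismatch = r$n_mismatch, n_gap = r$n_gap,
       n_gapopen = r$n_gapopen,
       query_span = c(r$q_start, r$q_end),
       target_span = c(r$t_start, r$t_end))
}

#' Local alignment score only
#'
#' @inheritParams local_align
#' @return integer raw score.
#' @export
local_score <- function(a, b, matrix = blosum62_matrix(),
                        gap_open = 11L, gap_extend = 1L) {
  c_sw_score(a, b, matrix, as.integer(gap_open), as.integer(gap_extend))
}

#' E-value and bit score from a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: strictly decreasing in the raw
#' score, linear in both the query length `m` and the database residue
#' count `n`.  The bit score is `(lambda * S - log(K)) / log(2)`.
#'
#' @param raw_score raw alignment score.
#' @param m query length (residues).
#' @param n database size (total residues searched).
#' @param params list with `lambda` and `K`, see [aa_karlin_params()].
#' @return numeric E-value (or bit score for [bit_score()]).
#' @export
estimate_evalue <- function(raw_score, m, n, params = aa_karlin_params()) {
  stopifnot(m > 0, n > 0)
  params$K * m * n * exp(-params$lambda * raw_score)
}

#' @rdname estimate_evalue
#' @export
bit_score <- function(raw_score, params = aa_karlin_params()) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}
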