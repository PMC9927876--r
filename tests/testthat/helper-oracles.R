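# Independent oracles and shared fixtures for the test suite.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_prot <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")
rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# Brute-force six-frame stop-free-run enumerator, written against
# Biostrings::translate rather than the package's own translator.
orf_oracle <- function(seq, ncbi_id, min_aa) {
  L <- nchar(seq)
  gc_tab <- Biostrings::getGeneticCode(ncbi_id)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (f in 0:2) {
      ncod <- (L - f) %/% 3
      if (ncod < 1) next
      sub <- substr(s, f + 1, f + 3 * ncod)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), genetic.code = gc_tab,
        no.init.codon = TRUE))
      ch <- strsplit(aa, "")[[1]]
      run_start <- NULL
      runs <- list()
      for (i in seq_along(ch)) {
        if (ch[i] == "*") {
          if (!is.null(run_start)) {
            runs[[length(runs) + 1]] <- c(run_start, i - 1)
            run_start <- NULL
          }
        } else if (is.null(run_start)) run_start <- i
      }
      if (!is.null(run_start)) runs[[length(runs) + 1]] <-
          c(run_start, length(ch))
      for (r in runs) {
        len <- r[2] - r[1] + 1
        if (len < min_aa) next
        s_start <- f + (r[1] - 1) * 3
        s_end <- f + r[2] * 3
        if (strand == "+") { a <- s_start; b <- s_end }
        else { a <- L - s_end; b <- L - s_start }
        out[[length(out) + 1]] <- data.frame(
          start = a, end = b, strand = strand, frame = f,
          protein = substr(aa, r[1], r[2]), aa_len = len,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      protein = character(0), aa_len = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, match(res$strand, c("+", "-")), res$frame), ]
  rownames(res) <- NULL
  res
}

# Plain-R affine-gap Smith-Waterman (score only), quadratic DP with
# explicit three-state recursion; independent of the C++ kernel.
sw_oracle_r <- function(a, b, mat, go, ge) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  H <- matrix(0, la + 1, lb + 1)
  E <- matrix(-Inf, la + 1, lb + 1)
  F <- matrix(-Inf, la + 1, lb + 1)
  best <- 0
  for (i in 2:(la + 1)) {
    for (j in 2:(lb + 1)) {
      E[i, j] <- max(E[i, j - 1] - ge, H[i, j - 1] - go - ge)
      F[i, j] <- max(F[i - 1, j] - ge, H[i - 1, j] - go - ge)
      sub <- mat[ca[i - 1], cb[j - 1]]
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Biostrings local alignment score, used as the large-scale alignment
# oracle.
sw_oracle_biostrings <- function(a, b, mat, go, ge) {
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = go, gapExtension = ge,
                                scoreOnly = TRUE)
}

# Small labelled database shared across search tests (deterministic).
test_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- make_reference_db(901L, n_viral = 21L,
                                              n_cellular = 16L)
    db
  }
})
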