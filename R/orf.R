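#' Stop-to-stop ORF prediction in six frames
#'
#' Enumerates every maximal stop-free codon run of at least `min_aa_len`
#' codons in all six reading frames (three forward, three on the reverse
#' complement).  Runs truncated by the contig ends are emitted as
#' open-ended partials, so no START codon is required -- appropriate for
#' partial virus genome recovery.  Coordinates are 0-based half-open on the
#' forward strand regardless of strand.
#'
#' @param seq contig nucleotide sequence (single string).
#' @param code genetic code from [genetic_code()].
#' @param min_aa_len minimum ORF length in amino acids (default 200, the
#'   floor used when screening culture transcriptomes for RdRps).
#' @param contig_id identifier recorded in the output.
#' @return data.frame with columns `contig_id`, `start`, `end`, `strand`,
#'   `frame`, `code_id`, `protein`, `aa_len`, sorted by
#'   (`start`, `strand`, `frame`).  The protein never contains `"*"`.
#' @export
predict_orfs <- function(seq, code = genetic_code("standard"),
                         min_aa_len = 200L, contig_id = "contig") {
  stopifnot(min_aa_len >= 1L)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 3L) {
    return(empty_orf_frame())
  }
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      if (ncod < min_aa_len) next
      sub <- substr(s, f + 1L, f + 3L * ncod)
      aa <- translate_seq(sub, code)
      runs <- stopfree_runs(aa, min_aa_len)
      if (nrow(runs) == 0) next
      # codon-index run [i, j] (1-based inclusive) -> strand-local nt coords
      s_start <- f + (runs$i - 1L) * 3L
      s_end <- f + runs$j * 3L
      if (strand == "+") {
        start <- s_start; end <- s_end
      } else {
        start <- L - s_end; end <- L - s_start
      }
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contig_id, start = start, end = end, strand = strand,
        frame = f, code_id = code$code_id,
        protein = substring(aa, runs$i, runs$j),
        aa_len = runs$j - runs$i + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_orf_frame())
  res <- do.call(rbind, out)
  res <- res[order(res$start, match(res$strand, c("+", "-")), res$frame), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_orf_frame <- function() {
  data.frame(contig_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), frame = integer(0),
             code_id = character(0), protein = character(0),
             aa_len = integer(0), stringsAsFactors = FALSE)
}

# Maximal runs of non-stop codons of length >= min_len in a translated
# frame; returns 1-based inclusive codon indices.
stopfree_runs <- function(aa, min_len) {
  ncod <- nchar(aa)
  stops <- which(strsplit(aa, "", fixed = TRUE)[[1]] == "*")
  bounds <- c(0L, stops, ncod + 1L)
  i <- bounds[-length(bounds)] + 1L
  j <- bounds[-1L] - 1L
  keep <- (j - i + 1L) >= min_len
  data.frame(i = i[keep], j = j[keep])
}

#' Ambigrammatic ORF detection
#'
#' An ORF is called ambigrammatic when the reverse-complement strand is
#' stop-free, in at least one of its three frames, over at least
#' `min_overlap_frac` of the ORF interval.  Narnavirus-like genomes carry
#' such ORFs, with the reverse strand retaining coding capacity.
#'
#' @param orf a single-row data.frame (or list) with `start` and `end`
#'   0-based half-open forward-strand coordinates, as produced by
#'   [predict_orfs()].
#' @param seq the contig nucleotide sequence the ORF belongs to.
#' @param code genetic code used to define stop codons on the reverse
#'   strand.
#' @param min_overlap_frac minimum stop-free fraction of the ORF interval
#'   (default 0.95).
#' @return logical.
#' @export
detect_ambigrammatic <- function(orf, seq, code = genetic_code("standard"),
                                 min_overlap_frac = 0.95) {
  seq <- toupper(seq)
  L <- nchar(seq)
  start <- as.integer(orf$start)
  end <- as.integer(orf$end)
  stopifnot(start >= 0, end <= L, end > start)
  ilen <- end - start
  rc <- revcomp(seq)
  for (f in 0:2) {
    ncod <- (L - f) %/% 3L
    if (ncod < 1L) next
    aa <- translate_seq(substr(rc, f + 1L, f + 3L * ncod), code)
    stops_rc <- (which(strsplit(aa, "", fixed = TRUE)[[1]] == "*") - 1L) * 3L + f
    # forward-strand interval of each reverse-strand stop codon
    stop_fwd_start <- L - (stops_rc + 3L)
    stop_fwd_end <- L - stops_rc
    inb <- stop_fwd_end > start & stop_fwd_start < end
    ss <- sort(pmax(stop_fwd_start[inb], start))
    ee <- sort(pmin(stop_fwd_end[inb], end))
    # longest stop-free stretch within [start, end): gaps between successive
    # (disjoint, sorted) stop-codon intervals, plus the two flanks
    free <- if (length(ss) == 0) ilen else max(c(ss, end) - c(start, ee))
    if (free / ilen >= min_overlap_frac) return(TRUE)
  }
  FALSE
}
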