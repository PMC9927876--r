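#' Map reads to reference contigs by exact seeding
#'
#' Each read nominates candidate placements via an exact match of its
#' first `k` nucleotides against an index of all reference k-mer
#' positions, and is assigned where the full read matches the reference
#' without mismatch (reads in this package's projects are error-free by
#' the generator contract, so ungapped extension reduces to exact
#' substring verification).  A read matching several references equally is
#' assigned to the lexicographically first reference id, which makes the
#' counts deterministic.  Reads with no valid placement are counted as
#' unassigned.
#'
#' @param reads character vector of read sequences.
#' @param refs named character vector of reference sequences (names are
#'   contig ids).
#' @param k seed length (default 25); must not exceed the shortest read.
#' @return list with `counts` (named integer vector per reference, in
#'   `names(refs)` order), `unassigned` (integer) and `total` (integer).
#' @export
map_reads <- function(reads, refs, k = 25L) {
  stopifnot(length(refs) > 0, !is.null(names(refs)))
  total <- length(reads)
  counts <- setNames(integer(length(refs)), names(refs))
  if (total == 0) return(list(counts = counts, unassigned = 0L, total = 0L))
  if (min(nchar(reads)) < k) stop("seed length k exceeds shortest read")
  ref_dt <- data.table::rbindlist(lapply(seq_along(refs), function(i) {
    s <- refs[[i]]
    n <- nchar(s)
    if (n < k) return(NULL)
    data.table::data.table(kmer = substring(s, 1:(n - k + 1L), k:n),
                           ref = i, pos = 1:(n - k + 1L))
  }))
  if (nrow(ref_dt) == 0) {
    return(list(counts = counts, unassigned = total, total = total))
  }
  data.table::setkey(ref_dt, kmer)
  read_dt <- data.table::data.table(read = seq_len(total),
                                    kmer = substr(reads, 1L, k),
                                    len = nchar(reads))
  cand <- ref_dt[read_dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(cand) == 0) {
    return(list(counts = counts, unassigned = total, total = total))
  }
  cand[, end := pos + len - 1L]
  cand <- cand[end <= nchar(refs)[ref]]
  if (nrow(cand) > 0) {
    ok <- substring(refs[cand$ref], cand$pos, cand$end) == reads[cand$read]
    cand <- cand[ok]
  }
  if (nrow(cand) > 0) {
    cand[, ref_id := names(refs)[ref]]
    assign <- cand[, .(ref_id = min(ref_id)), by = "read"]
    tab <- table(assign$ref_id)
    counts[names(tab)] <- as.integer(tab)
  }
  assigned <- sum(counts)
  list(counts = counts, unassigned = total - assigned, total = total)
}

#' Reads per million
#'
#' @param mapped reads mapped to the contig.
#' @param total total reads in the library; must be positive.
#' @return `mapped / total * 1e6`.
#' @export
reads_per_million <- function(mapped, total) {
  if (any(total <= 0)) stop("total read count must be positive")
  mapped / total * 1e6
}

#' Transcripts per million from counts and feature lengths
#'
#' Counts are first divided by feature length in kilobases, then the rates
#' are normalised to sum to one million over the supplied features (the
#' caller chooses the normalisation set, e.g. taxonomically assigned
#' contigs only).
#'
#' @param counts integer vector of mapped reads per feature.
#' @param lengths_nt feature lengths in nucleotides.
#' @return numeric vector of TPM values summing to 1e6 (all-zero counts
#'   return all zeros).
#' @export
tpm_from_counts <- function(counts, lengths_nt) {
  stopifnot(length(counts) == length(lengths_nt), all(lengths_nt > 0))
  rate <- counts / (lengths_nt / 1e3)
  s <- sum(rate)
  if (s == 0) return(rep(0, length(counts)))
  rate / s * 1e6
}

#' Cross-library index-hopping filter
#'
#' Applies the abundance rule for cross-library contamination: within a
#' cluster of libraries carrying the same sequence, the maximum-abundance
#' library always passes, and any library whose reads-per-million falls
#' strictly below `threshold_frac` times the maximum is flagged as a
#' likely index-hopping artefact.  A library exactly at the threshold
#' passes (the rule is a strict "less than").  The filter is idempotent
#' and does not depend on row order.
#'
#' @param abund data.frame with columns `contig_id`, `library_id`, `rpm`
#'   for one sequence cluster (one row per library occurrence).
#' @param threshold_frac abundance fraction threshold (default 0.001,
#'   i.e. 0.1 per cent).
#' @return the input with columns `flag` (`"pass"` or `"index_hopping"`)
#'   and `evidence` appended.
#' @export
cross_library_filter <- function(abund, threshold_frac = 0.001) {
  stopifnot(nrow(abund) >= 1, all(c("contig_id", "library_id", "rpm")
                                  %in% names(abund)))
  max_rpm <- max(abund$rpm)
  cut <- threshold_frac * max_rpm
  hopped <- abund$rpm < cut
  abund$flag <- ifelse(hopped, "index_hopping", "pass")
  abund$evidence <- ifelse(
    hopped,
    sprintf("rpm %.4g < %.4g (%.2g x max rpm %.4g)", abund$rpm, cut,
            threshold_frac, max_rpm),
    "")
  abund
}

#' Ubiquitous reagent-contaminant filter
#'
#' A sequence observed at 100 per cent nucleotide identity across a large
#' fraction of libraries is assumed to originate from environmental or
#' sequencing-associated contamination rather than independent infections,
#' and is flagged `reagent_contaminant`.
#'
#' @param identity percent nucleotide identity between the occurrences
#'   (full-length).
#' @param prevalence number of libraries carrying the sequence.
#' @param n_libraries total libraries in the project.
#' @param min_prevalence_frac prevalence fraction triggering the flag
#'   (default 0.10).
#' @return `"reagent_contaminant"` or `"pass"`.
#' @export
ubiquity_contaminant_filter <- function(identity, prevalence, n_libraries,
                                        min_prevalence_frac = 0.10) {
  stopifnot(n_libraries >= 1, prevalence <= n_libraries)
  if (identity == 100 && prevalence / n_libraries >= min_prevalence_frac) {
    "reagent_contaminant"
  } else {
    "pass"
  }
}

#' Greedy read-based contig extension
#'
#' Automates terminus extension: at each round, reads overlapping a
#' terminus by at least `min_overlap` exactly are collected and the
#' terminus is extended by the per-position majority consensus of their
#' overhangs.  A consensus tie truncates the extension at that position
#' and stops further extension of that terminus.  The interior of the
#' contig is never altered and the input contig is always a substring of
#' the output.
#'
#' @param seq contig nucleotide sequence.
#' @param reads character vector of (error-free) reads from the same
#'   library.
#' @param min_overlap minimum exact terminal overlap in nt (default 31).
#' @param max_rounds maximum extension rounds per call (default 20).
#' @return the extended sequence.
#' @export
extend_contig <- function(seq, reads, min_overlap = 31L, max_rounds = 20L) {
  seq <- toupper(seq)
  stopifnot(nchar(seq) >= min_overlap)
  right_open <- TRUE
  left_open <- TRUE
  for (round in seq_len(max_rounds)) {
    grew <- FALSE
    if (right_open) {
      r <- extend_terminus_once(seq, reads, min_overlap, "right")
      if (r$tie || !r$extended) right_open <- FALSE
      if (nchar(r$seq) > nchar(seq)) grew <- TRUE
      seq <- r$seq
    }
    if (left_open) {
      rl <- extend_terminus_once(seq, reads, min_overlap, "left")
      if (rl$tie || !rl$extended) left_open <- FALSE
      if (nchar(rl$seq) > nchar(seq)) grew <- TRUE
      seq <- rl$seq
    }
    if (!grew) break
  }
  seq
}

# One extension round at a terminus; returns list(seq, extended, tie).
# Overhang consensus is taken per position outward from the contig end.
extend_terminus_once <- function(seq, reads, min_overlap, side) {
  L <- nchar(seq)
  anchor <- if (side == "right") {
    substr(seq, L - min_overlap + 1L, L)
  } else {
    substr(seq, 1L, min_overlap)
  }
  hit <- regexpr(anchor, reads, fixed = TRUE)
  idx <- which(hit > 0)
  overhangs <- character(0)
  for (i in idx) {
    p <- hit[i]
    rl <- nchar(reads[i])
    if (side == "right") {
      lead <- p - 1L  # read part aligned inside the contig before the anchor
      if (lead > L - min_overlap) next
      if (lead > 0 &&
          substr(reads[i], 1L, lead) !=
          substr(seq, L - min_overlap + 1L - lead, L - min_overlap)) next
      oh <- substr(reads[i], p + min_overlap, rl)
    } else {
      trail <- rl - (p + min_overlap - 1L)  # read part inside the contig
      if (trail > L - min_overlap) next
      if (trail > 0 &&
          substr(reads[i], p + min_overlap, rl) !=
          substr(seq, min_overlap + 1L, min_overlap + trail)) next
      oh <- str_rev(substr(reads[i], 1L, p - 1L))  # outward from the end
    }
    if (nchar(oh) > 0) overhangs <- c(overhangs, oh)
  }
  if (length(overhangs) == 0) {
    return(list(seq = seq, extended = FALSE, tie = FALSE))
  }
  maxlen <- max(nchar(overhangs))
  ext <- character(0)
  tie <- FALSE
  for (pos in seq_len(maxlen)) {
    ch <- substr(overhangs, pos, pos)
    ch <- ch[ch != ""]
    tab <- sort(table(ch), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) { tie <- TRUE; break }
    ext <- c(ext, names(tab)[1])
  }
  ext <- paste(ext, collapse = "")
  new_seq <- if (side == "right") paste0(seq, ext) else
    paste0(str_rev(ext), seq)
  list(seq = new_seq, extended = nchar(ext) > 0, tie = tie)
}

#' Compare virus abundance to the host rbcL yardstick
#'
#' The chloroplast rbcL gene serves as a host expression yardstick: a
#' virus whose read abundance is within an order of magnitude of (or
#' above) rbcL is compatible with active replication.
#'
#' @param virus_rpm virus reads-per-million.
#' @param rbcl_rpm rbcL reads-per-million, or NA when no rbcL reference is
#'   available.
#' @return list with `ratio` (`virus_rpm / rbcl_rpm`) and
#'   `magnitude_class`: `"comparable_or_higher"` when the ratio is at
#'   least 0.1 (log10 >= -1), `"lower"` otherwise, `"not_assessed"` when
#'   rbcL is unavailable.
#' @export
rbcl_comparison <- function(virus_rpm, rbcl_rpm) {
  if (is.na(rbcl_rpm)) {
    return(list(ratio = NA_real_, magnitude_class = "not_assessed"))
  }
  if (rbcl_rpm <= 0) stop("rbcl_rpm must be positive when supplied")
  ratio <- virus_rpm / rbcl_rpm
  list(ratio = ratio,
       magnitude_class = if (ratio >= 0.1) "comparable_or_higher" else "lower")
}

#' Cluster candidate sequences across libraries
#'
#' Groups sequences that are effectively the same molecule observed in
#' different libraries: members of a cluster share at least
#' `min_identity` nucleotide identity over at least `min_coverage` of
#' both sequences (single-linkage).  Identical sequences are clustered
#' without alignment.
#'
#' @param seqs character vector of nucleotide sequences.
#' @param min_identity fractional identity threshold (default 0.99).
#' @param min_coverage mutual coverage threshold (default 0.9).
#' @return integer vector of cluster ids (1-based, stable order).
#' @export
cluster_candidate_sequences <- function(seqs, min_identity = 0.99,
                                        min_coverage = 0.9) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  mat <- nt_matrix()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (find(i) == find(j)) next
      if (seqs[i] == seqs[j]) { union2(i, j); next }
      li <- nchar(seqs[i]); lj <- nchar(seqs[j])
      if (min(li, lj) / max(li, lj) < min_coverage) next
      al <- c_sw_align(seqs[i], seqs[j], mat, 12L, 2L)
      cov_i <- (al$q_end - al$q_start) / li
      cov_j <- (al$t_end - al$t_start) / lj
      ident <- if (al$aln_len > 0) al$n_id / al$aln_len else 0
      if (ident >= min_identity && cov_i >= min_coverage &&
          cov_j >= min_coverage) union2(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
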