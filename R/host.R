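#' Assign a contig to a kingdom by its closest homolog
#'
#' Six-frame translations of the contig are searched against the labelled
#' protein database and, when nucleotide references are supplied, the
#' contig is also searched directly at the nucleotide level; the best hit
#' by bit score across both routes determines the kingdom (and phylum).
#' A contig with no hit at the cutoff is an orphan.
#'
#' @param seq contig nucleotide sequence.
#' @param db labelled protein database ([read_reference_db()]).
#' @param nt_refs optional data.frame of nucleotide references with
#'   columns `id`, `seq`, `kingdom`, `phylum`.
#' @param cutoff E-value cutoff (default `1e-3`).
#' @param code genetic code for the frame translations.
#' @param index optional pre-built [kmer_index()] over `db$seq`.
#' @param min_seed_count seeding stringency passed to [search_protein()].
#' @param contig_id identifier for reporting.
#' @return list with `kingdom`, `phylum` (NA for orphans), `orphan`
#'   (logical), `best` (best hit row or NULL).
#' @export
assign_contig_taxonomy <- function(seq, db, nt_refs = NULL, cutoff = 1e-3,
                                   code = genetic_code("standard"),
                                   index = NULL, min_seed_count = 1L,
                                   contig_id = "contig") {
  best <- NULL
  frames <- six_frame_translations(seq, code)
  for (nm in names(frames)) {
    fseq <- frames[[nm]]
    if (nchar(fseq) < 10) next
    h <- search_protein(fseq, db, evalue_cutoff = cutoff, max_targets = 1L,
                        query_id = contig_id, index = index,
                        min_seed_count = min_seed_count)
    if (nrow(h) == 0) next
    if (is.null(best) || h$bitscore > best$bitscore ||
        (h$bitscore == best$bitscore && h$target_id < best$target_id)) {
      best <- h
    }
  }
  if (!is.null(nt_refs) && nrow(nt_refs) > 0) {
    ntdb <- data.frame(id = nt_refs$id, seq = nt_refs$seq,
                       kingdom = nt_refs$kingdom, phylum = nt_refs$phylum,
                       family = NA_character_, species = NA_character_,
                       is_viral = FALSE, is_rdrp = FALSE,
                       stringsAsFactors = FALSE)
    h <- search_protein(seq, ntdb, evalue_cutoff = cutoff, max_targets = 1L,
                        matrix = nt_matrix(), gap_open = 12L,
                        gap_extend = 2L, params = nt_karlin_params(),
                        k = 11L, query_id = contig_id)
    if (nrow(h) > 0 && (is.null(best) || h$bitscore > best$bitscore)) {
      best <- h
    }
  }
  if (is.null(best)) {
    return(list(kingdom = NA_character_, phylum = NA_character_,
                orphan = TRUE, best = NULL))
  }
  list(kingdom = best$kingdom, phylum = best$phylum, orphan = FALSE,
       best = best)
}

#' Kingdom-level profile of a library
#'
#' Summarises the taxonomic composition of a library: each contig is
#' assigned by [assign_contig_taxonomy()], contig abundances (TPM,
#' normalised over assigned contigs only) are summed per kingdom, and the
#' fraction of orphan contigs is reported.  The per-kingdom TPM always
#' sums to one million when at least one contig is assigned.
#'
#' @param contigs data.frame with columns `id`, `seq`.
#' @param counts named integer vector of mapped reads per contig id.
#' @param db labelled protein database.
#' @param library_id identifier.
#' @param cutoff E-value cutoff.
#' @param assignments optional precomputed data.frame (`id`, `kingdom`,
#'   `phylum`, `orphan`) to avoid re-searching.
#' @param ... passed to [assign_contig_taxonomy()].
#' @return list with `library_id`, `assigned_tpm` (named numeric),
#'   `orphan_fraction`, `n_contigs`, `dominant_eukaryote` (phylum with the
#'   highest TPM among Eukaryota-assigned contigs, or NA), `assignments`
#'   (per-contig data.frame with `tpm`).
#' @export
kingdom_profile <- function(contigs, counts, db, library_id = "library",
                            cutoff = 1e-3, assignments = NULL, ...) {
  stopifnot(all(contigs$id %in% names(counts)))
  if (is.null(assignments)) {
    rows <- lapply(seq_len(nrow(contigs)), function(i) {
      a <- assign_contig_taxonomy(contigs$seq[i], db, cutoff = cutoff,
                                  contig_id = contigs$id[i], ...)
      data.frame(id = contigs$id[i], kingdom = a$kingdom,
                 phylum = a$phylum, orphan = a$orphan,
                 stringsAsFactors = FALSE)
    })
    assignments <- do.call(rbind, rows)
  }
  assignments <- assignments[match(contigs$id, assignments$id), ,
                             drop = FALSE]
  n <- nrow(contigs)
  orphan_fraction <- if (n > 0) mean(assignments$orphan) else NA_real_
  assigned <- which(!assignments$orphan)
  tpm <- rep(0, n)
  if (length(assigned) > 0) {
    tpm[assigned] <- tpm_from_counts(counts[contigs$id[assigned]],
                                     nchar(contigs$seq[assigned]))
  }
  assignments$tpm <- tpm
  assigned_tpm <- if (length(assigned) > 0) {
    tapply(tpm[assigned], assignments$kingdom[assigned], sum)
  } else numeric(0)
  assigned_tpm <- setNames(as.numeric(assigned_tpm), names(assigned_tpm))
  euk <- assigned[assignments$kingdom[assigned] %in% "Eukaryota"]
  dominant <- NA_character_
  if (length(euk) > 0) {
    by_phy <- tapply(tpm[euk], assignments$phylum[euk], sum)
    dominant <- names(by_phy)[which.max(by_phy)]
  }
  list(library_id = library_id, assigned_tpm = assigned_tpm,
       orphan_fraction = orphan_fraction, n_contigs = n,
       dominant_eukaryote = dominant, assignments = assignments)
}

#' Load the family-to-host-range map
#'
#' A small editable table shipped with the package mapping virus families
#' to the kingdom(s) of their known hosts; used to decide whether a
#' candidate's family is prokaryote-infecting.
#'
#' @param path optional path to an alternative TSV (columns `family`,
#'   `host_kingdom`).
#' @return data.frame.
#' @export
family_host_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "family_host_map.tsv",
                        package = "rdrpscout")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Propose a host for a viral candidate
#'
#' The default attribution in a mono-strain culture is the dominant
#' eukaryotic lineage of the library.  When the candidate's family is
#' known to infect prokaryotes (per the host-range map) and the library
#' carries bacterial contigs, the proposal switches to Bacteria -- the
#' pattern seen for levivirus-like sequences co-occurring with bacterial
#' contaminants.
#'
#' @param family candidate virus family (from
#'   [classify_nearest_reference()]).
#' @param profile library profile from [kingdom_profile()].
#' @param host_map host-range map, see [family_host_map()].
#' @return list with `proposed_host` and `rationale`.
#' @export
propose_host <- function(family, profile, host_map = family_host_map()) {
  if (length(profile$assigned_tpm) == 0) {
    return(list(proposed_host = "not_assessed",
                rationale = "no assigned contigs in library"))
  }
  hk <- host_map$host_kingdom[host_map$family == family]
  prok <- length(hk) > 0 && any(hk == "Bacteria")
  bact_tpm <- profile$assigned_tpm["Bacteria"]
  if (prok && !is.na(bact_tpm) && bact_tpm > 0) {
    return(list(proposed_host = "Bacteria",
                rationale = sprintf(
                  "%s is prokaryote-infecting and bacterial contigs are present (%.0f TPM)",
                  family, bact_tpm)))
  }
  if (is.na(profile$dominant_eukaryote)) {
    return(list(proposed_host = "not_assessed",
                rationale = "no eukaryotic contigs assigned"))
  }
  list(proposed_host = profile$dominant_eukaryote,
       rationale = sprintf("dominant eukaryotic lineage of %s",
                           profile$library_id))
}

#' Screen a candidate against the host genome for endogenous origin
#'
#' A candidate whose nucleotide sequence aligns to the host genome with a
#' strong E-value over a substantial fraction of its length most likely
#' represents an endogenous viral element (EVE) -- the trace of a past
#' integration -- rather than an exogenous replicating virus.  Alignment
#' is seeded with exact `seed_k`-mers (both strands of the candidate) and
#' refined by local alignment inside a window around each seed.
#'
#' @param candidate_nt candidate nucleotide sequence.
#' @param genome named character vector of host genome sequences (or a
#'   FASTA path); NULL when no genome is available.
#' @param eve_evalue_cutoff E-value at or below which the match supports
#'   endogenous origin (default `1e-10`).
#' @param eve_cov_min minimum fraction of the candidate aligned (default
#'   0.5).
#' @param seed_k nucleotide seed length (default 11).
#' @return list with `verdict` (`"likely_EVE"`, `"exogenous"`,
#'   `"no_genome"`), `best_evalue`, `coverage_frac`, `genome_id`.
#' @export
detect_eve <- function(candidate_nt, genome, eve_evalue_cutoff = 1e-10,
                       eve_cov_min = 0.5, seed_k = 11L) {
  if (is.null(genome) || length(genome) == 0) {
    return(list(verdict = "no_genome", best_evalue = NA_real_,
                coverage_frac = NA_real_, genome_id = NA_character_))
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  candidate_nt <- toupper(candidate_nt)
  Lc <- nchar(candidate_nt)
  n_total <- sum(nchar(genome))
  mat <- nt_matrix()
  best <- NULL
  for (strand_seq in c(candidate_nt, revcomp(candidate_nt))) {
    probes_at <- unique(pmin(seq(1L, max(Lc - seed_k + 1L, 1L), by = 50L),
                             Lc - seed_k + 1L))
    probes <- substring(strand_seq, probes_at, probes_at + seed_k - 1L)
    for (gi in seq_along(genome)) {
      gseq <- genome[[gi]]
      hit_pos <- integer(0)
      for (p in seq_along(probes)) {
        m <- regexpr(probes[p], gseq, fixed = TRUE)
        if (m > 0) hit_pos <- c(hit_pos, as.integer(m) - probes_at[p] + 1L)
      }
      if (length(hit_pos) == 0) next
      for (anchor in unique(pmax(hit_pos, 1L))) {
        ws <- max(anchor - 200L, 1L)
        we <- min(anchor + Lc + 200L, nchar(gseq))
        window <- substr(gseq, ws, we)
        al <- c_sw_align(strand_seq, window, mat, 12L, 2L)
        ev <- estimate_evalue(al$score, Lc, n_total, nt_karlin_params())
        cov <- (al$q_end - al$q_start) / Lc
        if (is.null(best) || ev < best$ev) {
          best <- list(ev = ev, cov = cov, id = names(genome)[gi])
        }
      }
    }
  }
  if (is.null(best)) {
    return(list(verdict = "exogenous", best_evalue = NA_real_,
                coverage_frac = 0, genome_id = NA_character_))
  }
  verdict <- if (best$ev <= eve_evalue_cutoff && best$cov >= eve_cov_min) {
    "likely_EVE"
  } else "exogenous"
  list(verdict = verdict, best_evalue = best$ev, coverage_frac = best$cov,
       genome_id = best$id)
}
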