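#' Default discovery configuration
#'
#' All triage thresholds in one place.  Defaults follow the workflow's
#' stated operating points: 200-aa ORF floor, 1e-3 similarity-search
#' E-value cutoff, 1e-5 profile retention cutoff with a 1e-3 grey-zone
#' boundary, 0.1 per cent cross-library abundance threshold, and a 1e-10
#' E-value with 50 per cent coverage for endogenous-element calls.
#' `min_target_coverage` implements the coverage quality check applied to
#' similarity-search candidates: a hit must span at least that fraction
#' of the matched reference RdRp, which removes spurious short
#' high-scoring segment matches.
#'
#' @param seed integer seed controlling the stochastic components
#'   (profile-scan null distributions).
#' @return named list of settings.
#' @export
default_config <- function(seed = 1L) {
  list(seed = seed,
       min_aa_len = 200L,
       search_evalue = 1e-3,
       profile_retain_evalue = 1e-5,
       profile_weak_evalue = 1e-3,
       structure_confidence = 90,
       hop_threshold = 0.001,
       reagent_min_prevalence = 0.10,
       cluster_identity = 0.99,
       cluster_coverage = 0.9,
       eve_evalue = 1e-10,
       eve_cov_min = 0.5,
       codes = c("standard", "mito", "plastid"),
       map_k = 25L,
       seed_k = 4L,
       orf_min_seed_count = 1L,
       translated_min_seed_count = 3L,
       min_target_coverage = 0.2,
       n_shuffles = 200L,
       min_overlap = 31L,
       max_rounds = 20L,
       structure_scores = NULL)
}

#' Genome completeness heuristic
#'
#' A candidate is called `full_length` when its RdRp ORF is stop-bounded
#' on both sides within the contig and the contig extends at least
#' `margin` nucleotides beyond the ORF on each side; anything else is
#' `partial`.  This is a stated, configurable heuristic, not a claim of
#' equivalence with expert genome curation.
#'
#' @param seq contig sequence.
#' @param orf one-row ORF data.frame (`start`, `end`, `strand`) from
#'   [predict_orfs()], or NULL.
#' @param code genetic code the ORF was predicted under.
#' @param margin required flank in nt (default 50).
#' @return `"full_length"` or `"partial"`.
#' @export
genome_status <- function(seq, orf, code = genetic_code("standard"),
                          margin = 50L) {
  if (is.null(orf) || nrow(orf) == 0) return("partial")
  L <- nchar(seq)
  if (orf$strand == "+") {
    s <- toupper(seq); ls <- orf$start; le <- orf$end
  } else {
    s <- revcomp(seq); ls <- L - orf$end; le <- L - orf$start
  }
  if (ls < margin || (L - le) < margin) return("partial")
  prev_codon <- substr(s, ls - 2L, ls)
  next_codon <- substr(s, le + 1L, le + 3L)
  if (prev_codon %in% code$stops && next_codon %in% code$stops) {
    "full_length"
  } else "partial"
}

#' Run the full discovery workflow over a project directory
#'
#' Stages, in order: six-frame ORF prediction (standard code); best-hit
#' protein search of every ORF against the full reference database;
#' translated (six-frame) search of every contig against the RdRp-only
#' database; reciprocal confirmation of all candidates against the full
#' mixed database; profile/motif rescue of orphan ORFs; read mapping and
#' abundance estimation; cross-library index-hopping and
#' reagent-contaminant filters; greedy read-based contig extension;
#' re-annotation under alternative genetic codes; kingdom-level host
#' profiling and host proposal; endogenous-viral-element screening; and
#' report assembly.  Every discard is logged with the rule that fired.
#' The run is deterministic given the configuration seed and invariant to
#' library processing order.
#'
#' @param project_dir project directory (see [make_project()] /
#'   [read_project()]).
#' @param config see [default_config()].
#' @param out_dir optional output directory; when given,
#'   `candidates.tsv`, `kingdom_profiles.tsv`, `filters.tsv`, `eve.tsv`,
#'   `discovery_log.tsv` and `run.json` are written.
#' @return list with `candidates`, `profiles`, `filters`, `eve`, `log`
#'   data.frames.
#' @export
run_discovery <- function(project_dir, config = default_config(),
                          out_dir = NULL) {
  project <- read_project(project_dir)
  db <- project$db
  rdrp_db <- db[db$is_rdrp, , drop = FALSE]
  if (nrow(rdrp_db) == 0) stop("reference database contains no RdRps")
  idx_full <- kmer_index(db$seq, k = config$seed_k)
  profiles <- rdrp_profiles(db)
  host_map <- family_host_map()
  tlen <- setNames(nchar(db$seq), db$id)
  code_std <- genetic_code("standard")
  logs <- list()
  note <- function(stage, lib, contig, decision, detail = "") {
    logs[[length(logs) + 1L]] <<- data.frame(
      stage = stage, library_id = lib, contig_id = contig,
      decision = decision, detail = detail, stringsAsFactors = FALSE)
  }
  libs <- names(project$libraries)
  cands <- list()
  lib_data <- list()
  for (lib in libs) {
    ld <- project$libraries[[lib]]
    contigs <- ld$contigs
    refs <- setNames(contigs$seq, contigs$id)
    mp <- map_reads(ld$reads, refs, k = config$map_k)
    rpm <- reads_per_million(mp$counts, mp$total)
    rbcl_rpm <- NA_real_
    if (!is.null(ld$rbcl_path)) {
      rref <- read_fasta(ld$rbcl_path)
      mp_rbcl <- map_reads(ld$reads, rref, k = config$map_k)
      rbcl_rpm <- reads_per_million(sum(mp_rbcl$counts), mp_rbcl$total)
    }
    lib_data[[lib]] <- list(contigs = contigs, counts = mp$counts,
                            unassigned = mp$unassigned, total = mp$total,
                            rpm = rpm, rbcl_rpm = rbcl_rpm,
                            reads = ld$reads, genome_path = ld$genome_path)
    seen <- character(0)
    orphan_orfs <- list()
    tax_rows <- list()
    for (ci in seq_len(nrow(contigs))) {
      cid <- contigs$id[ci]
      orfs <- predict_orfs(contigs$seq[ci], code_std,
                           min_aa_len = config$min_aa_len, contig_id = cid)
      best_cand <- NULL
      for (oi in seq_len(nrow(orfs))) {
        h <- search_protein(orfs$protein[oi], db,
                            evalue_cutoff = config$search_evalue,
                            max_targets = 1L, k = config$seed_k,
                            min_seed_count = config$orf_min_seed_count,
                            query_id = cid, index = idx_full)
        if (nrow(h) == 0) {
          orphan_orfs[[length(orphan_orfs) + 1L]] <- orfs[oi, ]
          next
        }
        if (!(h$is_viral && h$is_rdrp)) next
        cov <- (h$tend - h$tstart) / tlen[[h$target_id]]
        if (cov < config$min_target_coverage) {
          note("orf_search", lib, cid, "discard",
               sprintf("viral hit %s below target coverage (%.2f)",
                       h$target_id, cov))
          next
        }
        if (is.null(best_cand) || h$bitscore > best_cand$hit$bitscore) {
          best_cand <- list(hit = h, protein = orfs$protein[oi],
                            orf = orfs[oi, ])
        }
      }
      if (!is.null(best_cand)) {
        cands[[length(cands) + 1L]] <- list(
          library_id = lib, contig_id = cid, seq = contigs$seq[ci],
          route = "orf_blastp_like", protein = best_cand$protein,
          hit = best_cand$hit)
        seen <- c(seen, cid)
      }
      # one six-frame scan serves both the taxonomy assignment and the
      # sensitive translated RdRp route
      fs <- scan_contig_frames(contigs$seq[ci], db, idx_full, config,
                               code_std, contig_id = cid)
      tax_rows[[ci]] <- data.frame(
        id = cid,
        kingdom = if (is.null(fs$tax)) NA_character_ else fs$tax$kingdom,
        phylum = if (is.null(fs$tax)) NA_character_ else fs$tax$phylum,
        orphan = is.null(fs$tax), stringsAsFactors = FALSE)
      if (!(cid %in% seen) && !is.null(fs$rdrp)) {
        h <- fs$rdrp
        cov <- (h$tend - h$tstart) / tlen[[h$target_id]]
        if (cov < config$min_target_coverage) {
          note("translated_search", lib, cid, "discard",
               sprintf("hit %s below target coverage (%.2f)",
                       h$target_id, cov))
        } else {
          frames <- six_frame_translations(contigs$seq[ci], code_std)
          fr <- frames[[paste0(h$strand, h$frame)]]
          prot <- substr(fr, h$qstart + 1L, h$qend)
          cands[[length(cands) + 1L]] <- list(
            library_id = lib, contig_id = cid, seq = contigs$seq[ci],
            route = "translated_search", protein = prot, hit = h)
        }
      }
    }
    lib_data[[lib]]$assignments <- do.call(rbind, tax_rows)
    # profile/motif rescue of orphan ORFs
    for (orf in orphan_orfs) {
      prot <- orf$protein
      oseed <- derive_seed(config$seed,
                           sum(utf8ToInt(paste0(lib, orf$contig_id,
                                                orf$start))) %% 100000L)
      best_scan <- NULL
      for (pf in names(profiles)) {
        sc <- scan_profile(prot, profiles[[pf]],
                           n_shuffles = config$n_shuffles, seed = oseed,
                           db_size = length(profiles))
        if (!sc$scanned) next
        if (is.null(best_scan) ||
            sc$empirical_evalue < best_scan$evalue) {
          best_scan <- list(profile = pf, evalue = sc$empirical_evalue,
                            score = sc$best_score)
        }
      }
      if (is.null(best_scan)) next
      motif <- find_motifs_abc(prot)
      struct <- lookup_structure(config$structure_scores, orf$contig_id)
      dec <- curate_candidate(best_scan$evalue, struct$confidence,
                              struct$is_viral, motif,
                              curation_thresholds(
                                config$profile_retain_evalue,
                                config$profile_weak_evalue,
                                config$structure_confidence))
      if (dec$verdict == "retained") {
        cands[[length(cands) + 1L]] <- list(
          library_id = lib, contig_id = orf$contig_id,
          seq = contigs$seq[match(orf$contig_id, contigs$id)],
          route = "profile_motif", protein = prot,
          hit = NULL, profile = best_scan$profile,
          profile_evalue = best_scan$evalue, motif = motif)
      } else {
        note("profile_rescue", lib, orf$contig_id, dec$verdict,
             sprintf("profile %s e-value %.3g: %s", best_scan$profile,
                     best_scan$evalue, dec$reason))
      }
    }
  }
  # reciprocal confirmation
  confirmed <- list()
  for (cd in cands) {
    rc <- reciprocal_confirm(cd$protein, db,
                             evalue_cutoff = config$search_evalue,
                             k = config$seed_k,
                             min_seed_count = config$orf_min_seed_count,
                             index = idx_full, query_id = cd$contig_id)
    if (rc$status == "confirmed") {
      cd$reciprocal <- rc$best_hit
      confirmed[[length(confirmed) + 1L]] <- cd
    } else {
      note("reciprocal", cd$library_id, cd$contig_id, rc$status,
           if (!is.null(rc$best_hit)) {
             sprintf("best full-db hit %s (non-viral)",
                     rc$best_hit$target_id)
           } else "no hit in full database")
    }
  }
  res <- assemble_report(confirmed, lib_data, db, profiles, host_map,
                         config, note)
  logs_df <- if (length(logs) > 0) do.call(rbind, logs) else
    data.frame(stage = character(0), library_id = character(0),
               contig_id = character(0), decision = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  # merge notes recorded inside assemble_report
  logs_df <- rbind(logs_df, res$extra_logs)
  out <- list(candidates = res$candidates, profiles = res$profiles,
              filters = res$filters, eve = res$eve, log = logs_df)
  if (!is.null(out_dir)) write_discovery_outputs(out, out_dir, config)
  out
}

# One six-frame pass over the full database serving two purposes: the
# contig's best hit overall (taxonomy assignment) and its best hit among
# RdRps with the E-value referred to the RdRp-only database size (the
# sensitive translated route).
scan_contig_frames <- function(seq, db, index, config, code,
                               contig_id = "contig",
                               params = aa_karlin_params()) {
  mat <- blosum62_matrix()
  is_r <- db$is_rdrp
  n_full <- sum(nchar(db$seq))
  n_rdrp <- sum(nchar(db$seq[is_r]))
  frames <- six_frame_translations(seq, code)
  best_all <- NULL
  best_rdrp <- NULL
  upd <- function(cur, score, ti, nm, m) {
    if (is.null(cur) || score > cur$score ||
        (score == cur$score && db$id[ti] < db$id[cur$ti])) {
      list(score = score, ti = ti, frame = nm, m = m)
    } else cur
  }
  for (nm in names(frames)) {
    q <- frames[[nm]]
    m <- nchar(q)
    if (m < 10) next
    cand <- seed_nominate(q, index, config$seed_k,
                          config$translated_min_seed_count)
    if (length(cand) == 0) next
    scores <- c_sw_score_batch(q, db$seq[cand], mat, 11L, 1L)
    bi <- which.max(scores)
    best_all <- upd(best_all, scores[bi], cand[bi], nm, m)
    ri <- which(is_r[cand])
    if (length(ri) > 0) {
      bri <- ri[which.max(scores[ri])]
      best_rdrp <- upd(best_rdrp, scores[bri], cand[bri], nm, m)
    }
  }
  mk_hit <- function(b, n_db) {
    if (is.null(b)) return(NULL)
    ev <- estimate_evalue(b$score, b$m, n_db, params)
    if (ev > config$search_evalue) return(NULL)
    ti <- b$ti
    al <- c_sw_align(frames[[b$frame]], db$seq[ti], mat, 11L, 1L)
    data.frame(query_id = contig_id, target_id = db$id[ti],
               raw_score = b$score, bitscore = bit_score(b$score, params),
               evalue = ev, pct_identity = al$pct_identity,
               aln_len = al$aln_len, n_mismatch = al$n_mismatch,
               n_gapopen = al$n_gapopen, qstart = al$q_start,
               qend = al$q_end, tstart = al$t_start, tend = al$t_end,
               is_viral = db$is_viral[ti], is_rdrp = db$is_rdrp[ti],
               kingdom = db$kingdom[ti], phylum = db$phylum[ti],
               family = db$family[ti],
               strand = substr(b$frame, 1, 1),
               frame = as.integer(substr(b$frame, 2, 2)),
               stringsAsFactors = FALSE)
  }
  tax_hit <- mk_hit(best_all, n_full)
  rdrp_hit <- mk_hit(best_rdrp, n_rdrp)
  list(tax = if (is.null(tax_hit)) NULL else
         list(kingdom = tax_hit$kingdom, phylum = tax_hit$phylum,
              hit = tax_hit),
       rdrp = rdrp_hit)
}

lookup_structure <- function(structure_scores, contig_id) {
  if (is.null(structure_scores)) {
    return(list(confidence = NA_real_, is_viral = NA))
  }
  i <- match(contig_id, structure_scores$contig_id)
  if (is.na(i)) return(list(confidence = NA_real_, is_viral = NA))
  list(confidence = structure_scores$confidence[i],
       is_viral = structure_scores$hit_is_viral[i])
}

# Downstream half of the workflow: abundance, filters, extension,
# re-annotation, host profiling, EVE screen, report assembly.
assemble_report <- function(confirmed, lib_data, db, profiles, host_map,
                            config, note) {
  extra_logs <- list()
  note2 <- function(stage, lib, contig, decision, detail = "") {
    extra_logs[[length(extra_logs) + 1L]] <<- data.frame(
      stage = stage, library_id = lib, contig_id = contig,
      decision = decision, detail = detail, stringsAsFactors = FALSE)
  }
  empty_candidates <- data.frame(
    library_id = character(0), contig_id = character(0),
    detection_route = character(0), family = character(0),
    pct_identity = numeric(0), best_hit = character(0),
    evalue = numeric(0), bitscore = numeric(0), rpm = numeric(0),
    genome_status = character(0), code_id = character(0),
    motif_c = character(0), ambigrammatic = logical(0),
    rbcl_class = character(0), proposed_host = character(0),
    stringsAsFactors = FALSE)
  empty_filters <- data.frame(library_id = character(0),
                              contig_id = character(0), flag = character(0),
                              evidence = character(0),
                              stringsAsFactors = FALSE)
  empty_eve <- data.frame(library_id = character(0),
                          contig_id = character(0), verdict = character(0),
                          best_evalue = numeric(0),
                          coverage_frac = numeric(0),
                          stringsAsFactors = FALSE)
  kp_all <- compute_kingdom_profiles(lib_data, db, config)
  profiles_df <- kp_all$df
  if (length(confirmed) == 0) {
    return(list(candidates = empty_candidates, profiles = profiles_df,
                filters = empty_filters, eve = empty_eve,
                extra_logs = do.call(rbind, c(list(
                  data.frame(stage = character(0),
                             library_id = character(0),
                             contig_id = character(0),
                             decision = character(0),
                             detail = character(0),
                             stringsAsFactors = FALSE)), extra_logs))))
  }
  key <- vapply(confirmed, function(x) paste(x$library_id, x$contig_id),
                character(1))
  ord <- order(key)
  confirmed <- confirmed[ord]
  # abundance
  for (i in seq_along(confirmed)) {
    cd <- confirmed[[i]]
    confirmed[[i]]$rpm <-
      unname(lib_data[[cd$library_id]]$rpm[cd$contig_id])
  }
  # cross-library clustering and filters
  seqs <- vapply(confirmed, `[[`, character(1), "seq")
  clusters <- cluster_candidate_sequences(seqs, config$cluster_identity,
                                          config$cluster_coverage)
  n_libraries <- length(lib_data)
  flags <- rep("pass", length(confirmed))
  evidence <- rep("", length(confirmed))
  for (cl in unique(clusters)) {
    members <- which(clusters == cl)
    # index-hopping first: very low-abundance copies of a sequence that is
    # abundant in another library are explained by hopping
    ab <- data.frame(
      contig_id = vapply(confirmed[members], `[[`, character(1),
                         "contig_id"),
      library_id = vapply(confirmed[members], `[[`, character(1),
                          "library_id"),
      rpm = vapply(confirmed[members], `[[`, numeric(1), "rpm"),
      stringsAsFactors = FALSE)
    fl <- cross_library_filter(ab, config$hop_threshold)
    hop <- which(fl$flag == "index_hopping")
    flags[members[hop]] <- "index_hopping"
    evidence[members[hop]] <- fl$evidence[hop]
    # reagent-contaminant rule: the same sequence, at comparable abundance
    # (not explained by hopping), identical across a large fraction of
    # libraries
    surv <- members[flags[members] == "pass"]
    seq_groups <- split(surv, seqs[surv])
    for (grp in seq_groups) {
      libs_grp <- unique(vapply(confirmed[grp], `[[`, character(1),
                                "library_id"))
      if (length(libs_grp) < 2) next
      verdict <- ubiquity_contaminant_filter(
        100, length(libs_grp), n_libraries,
        config$reagent_min_prevalence)
      if (verdict == "reagent_contaminant") {
        flags[grp] <- "reagent_contaminant"
        evidence[grp] <- sprintf(
          "identical sequence in %d/%d libraries", length(libs_grp),
          n_libraries)
      }
    }
  }
  filters <- data.frame(
    library_id = vapply(confirmed, `[[`, character(1), "library_id"),
    contig_id = vapply(confirmed, `[[`, character(1), "contig_id"),
    flag = flags, evidence = evidence, stringsAsFactors = FALSE)
  for (i in which(flags != "pass")) {
    note2("contamination_filter", confirmed[[i]]$library_id,
          confirmed[[i]]$contig_id, flags[i], evidence[i])
  }
  # extension, re-annotation, host profiling, EVE, report
  rows <- list()
  eve_rows <- list()
  for (i in seq_along(confirmed)) {
    if (flags[i] != "pass") next
    cd <- confirmed[[i]]
    lib <- cd$library_id
    ldat <- lib_data[[lib]]
    ext <- extend_contig(cd$seq, ldat$reads,
                         min_overlap = config$min_overlap,
                         max_rounds = config$max_rounds)
    ann <- annotate_candidate(ext, cd, db, config)
    cls <- classify_nearest_reference(cd$protein, db)
    kp <- kp_all$kps[[lib]]
    host <- propose_host(cls$family, kp, host_map)
    rb <- rbcl_comparison(cd$rpm, ldat$rbcl_rpm)
    ev <- detect_eve(ext, ldat$genome_path,
                     eve_evalue_cutoff = config$eve_evalue,
                     eve_cov_min = config$eve_cov_min)
    eve_rows[[length(eve_rows) + 1L]] <- data.frame(
      library_id = lib, contig_id = cd$contig_id, verdict = ev$verdict,
      best_evalue = ev$best_evalue %||% NA_real_,
      coverage_frac = ev$coverage_frac %||% NA_real_,
      stringsAsFactors = FALSE)
    if (identical(ev$verdict, "likely_EVE")) {
      note2("eve_screen", lib, cd$contig_id, "excluded_eve",
            sprintf("matches host genome (E = %.3g, coverage %.2f)",
                    ev$best_evalue, ev$coverage_frac))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      library_id = lib, contig_id = cd$contig_id,
      detection_route = cd$route, family = cls$family,
      pct_identity = round(cls$pct_identity, 1),
      best_hit = if (!is.null(cd$hit)) cd$hit$target_id else
        cls$target_id,
      evalue = if (!is.null(cd$hit)) cd$hit$evalue else
        cd$profile_evalue,
      bitscore = if (!is.null(cd$hit)) round(cd$hit$bitscore, 1) else
        NA_real_,
      rpm = cd$rpm, genome_status = ann$status, code_id = ann$code_id,
      motif_c = ann$motif_c, ambigrammatic = ann$ambigrammatic,
      rbcl_class = rb$magnitude_class, proposed_host = host$proposed_host,
      stringsAsFactors = FALSE)
  }
  candidates <- if (length(rows) > 0) do.call(rbind, rows) else
    empty_candidates
  if (nrow(candidates) > 0) {
    candidates <- candidates[order(candidates$library_id,
                                   candidates$contig_id), , drop = FALSE]
    rownames(candidates) <- NULL
  }
  eve_df <- if (length(eve_rows) > 0) do.call(rbind, eve_rows) else
    empty_eve
  list(candidates = candidates, profiles = profiles_df, filters = filters,
       eve = eve_df,
       extra_logs = if (length(extra_logs) > 0) do.call(rbind, extra_logs)
       else data.frame(stage = character(0), library_id = character(0),
                       contig_id = character(0), decision = character(0),
                       detail = character(0), stringsAsFactors = FALSE))
}

# Re-annotate an (extended) candidate under the configured genetic codes:
# choose the (code, ORF) pair whose protein scores best against the
# candidate's nearest reference, preferring earlier codes on ties.
annotate_candidate <- function(ext_seq, cd, db, config) {
  target_seq <- if (!is.null(cd$hit)) {
    db$seq[match(cd$hit$target_id, db$id)]
  } else {
    cls <- classify_nearest_reference(cd$protein, db)
    db$seq[match(cls$target_id, db$id)]
  }
  mat <- blosum62_matrix()
  best <- NULL
  for (code_id in config$codes) {
    code <- genetic_code(code_id)
    orfs <- predict_orfs(ext_seq, code, min_aa_len = config$min_aa_len,
                         contig_id = cd$contig_id)
    for (oi in seq_len(nrow(orfs))) {
      s <- c_sw_score(orfs$protein[oi], target_seq, mat, 11L, 1L)
      if (is.null(best) || s > best$score) {
        best <- list(score = s, orf = orfs[oi, ], code = code,
                     code_id = code_id)
      }
    }
  }
  if (is.null(best)) {
    return(list(status = "partial", code_id = NA_character_,
                motif_c = NA_character_, ambigrammatic = NA))
  }
  motif <- if (nchar(best$orf$protein) >= 100) {
    find_motifs_abc(best$orf$protein)
  } else list(motif_C_triad = NA_character_)
  list(status = genome_status(ext_seq, best$orf, best$code),
       code_id = best$code_id,
       motif_c = motif$motif_C_triad %||% NA_character_,
       ambigrammatic = detect_ambigrammatic(best$orf, ext_seq, best$code))
}

compute_kingdom_profiles <- function(lib_data, db, config) {
  rows <- list()
  kps <- list()
  for (lib in names(lib_data)) {
    ldat <- lib_data[[lib]]
    kp <- kingdom_profile(ldat$contigs, ldat$counts, db,
                          library_id = lib,
                          cutoff = config$search_evalue,
                          assignments = ldat$assignments)
    kps[[lib]] <- kp
    if (length(kp$assigned_tpm) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        library_id = lib, kingdom = NA_character_, tpm = NA_real_,
        orphan_fraction = kp$orphan_fraction, n_contigs = kp$n_contigs,
        dominant_eukaryote = kp$dominant_eukaryote,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        library_id = lib, kingdom = names(kp$assigned_tpm),
        tpm = unname(kp$assigned_tpm),
        orphan_fraction = kp$orphan_fraction, n_contigs = kp$n_contigs,
        dominant_eukaryote = kp$dominant_eukaryote,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows) == 0) {
    data.frame(library_id = character(0), kingdom = character(0),
               tpm = numeric(0), orphan_fraction = numeric(0),
               n_contigs = integer(0),
               dominant_eukaryote = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  list(df = df, kps = kps)
}

write_discovery_outputs <- function(out, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(out$candidates, "candidates.tsv")
  wt(out$profiles, "kingdom_profiles.tsv")
  wt(out$filters, "filters.tsv")
  wt(out$eve, "eve.tsv")
  wt(out$log, "discovery_log.tsv")
  run_info <- list(
    package = "rdrpscout",
    version = as.character(utils::packageVersion("rdrpscout")),
    seed = config$seed,
    thresholds = config[setdiff(names(config), "structure_scores")])
  jsonlite::write_json(run_info, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
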