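#' Default virus roster for synthetic projects
#'
#' Twelve planted viruses spanning the five genome architectures and six
#' source families, at protein divergences from 20 to 50 per cent --
#' the regime where sequence-similarity detection still works but
#' identities to the closest reference are low.  Two high-abundance
#' viruses act as index-hopping sources; the levivirus-like entry is
#' placed in a bacteria-carrying library to exercise prokaryotic host
#' attribution.
#'
#' @return list of per-virus specs (`template`, `library`, `frac`,
#'   `status`).
#' @export
default_virus_roster <- function() {
  v <- function(name, arch, fam, div, lib, frac, status) {
    list(template = virus_template(name, arch, fam, div),
         library = lib, frac = frac, status = status)
  }
  list(
    v("V01narna", "narna_single_orf_ambigrammatic", "Narnaviridae", 0.20,
      "L01", 0.02, "full"),
    v("V02toti", "toti_cp_rdrp", "Totiviridae", 0.25, "L02", 0.02, "full"),
    v("V03levi", "narna_single_orf_ambigrammatic", "Leviviridae", 0.30,
      "L03", 0.002, "partial"),
    v("V04mito", "mito_code_single_orf", "Mitoviridae", 0.25, "L04",
      0.002, "full"),
    v("V05mito", "mito_code_single_orf", "Mitoviridae", 0.40, "L05",
      0.002, "full"),
    v("V06narna", "narna_single_orf_ambigrammatic", "Narnaviridae", 0.45,
      "L06", 0.002, "full"),
    v("V07toti", "toti_cp_rdrp", "Totiviridae", 0.35, "L07", 0.002, "full"),
    v("V08toti", "toti_cp_rdrp", "Totiviridae", 0.50, "L08", 0.002,
      "partial"),
    v("V09partiti", "partiti_bisegmented", "Partitiviridae", 0.30, "L09",
      0.002, "full"),
    v("V10partiti", "partiti_bisegmented", "Partitiviridae", 0.45, "L10",
      0.002, "full"),
    v("V11marna", "marna_polyprotein", "Marnaviridae", 0.20, "L11",
      0.005, "full"),
    v("V12marna", "marna_polyprotein", "Marnaviridae", 0.50, "L12",
      0.002, "partial"))
}

#' Default configuration for a synthetic culture-transcriptome project
#'
#' Twenty libraries at 1e5 error-free 100-nt reads each.  Two rRNA-like
#' contigs absorb 80 per cent of every library's reads, mimicking
#' libraries prepared without rRNA depletion, so everything else --
#' including viruses -- is a small fraction of reads.  Each library
#' carries host transcripts derived from reference proteins of its
#' lineage (including one rbcL-like gene at 0.5 per cent of reads) and
#' unassignable random contigs tuned so about half of contigs are
#' orphans.  Twelve viruses are planted in libraries L01--L12, two
#' index-hopped copies (single reads, below 0.1 per cent of the source
#' abundance by construction) land in L13 and L14, L15--L20 stay
#' virus-free, a reagent contaminant is shared identically by 15 of 20
#' libraries, and one endogenous viral element is planted in library
#' L13's host genome.
#'
#' @param n_libraries,depth,read_len library count and sequencing depth.
#' @return configuration list consumed by [make_project()].
#' @export
default_project_config <- function(n_libraries = 20L, depth = 1e5L,
                                   read_len = 100L) {
  phyla <- c("Bacillariophyta", "Haptophyta", "Chlorophyta", "Rhodophyta",
             "Dinophyceae")
  list(
    n_libraries = n_libraries, depth = depth, read_len = read_len,
    host_phyla = rep(phyla, length.out = n_libraries),
    n_host_transcripts = 16L, host_divergence = 0.05,
    n_orphan_contigs = 16L, orphan_len = 800L,
    rrna_fracs = c(0.5, 0.3), rrna_lens = c(3000L, 2000L),
    rbcl_frac = 0.005, orphan_frac_each = 0.001,
    bacterial_libraries = c("L03", "L12", "L13"),
    n_bacterial_contigs = 4L, bacterial_frac_total = 0.01,
    viruses = default_virus_roster(),
    hops = list(list(source = "V01narna", source_library = "L01",
                     target_library = "L13", n_reads = 1L),
                list(source = "V02toti", source_library = "L02",
                     target_library = "L14", n_reads = 1L)),
    reagent = list(prevalence = 15L, frac = 0.001, family = "Mitoviridae",
                   divergence = 0.15),
    eve = list(library = "L13", family = "Qinviridae", divergence = 0.30,
               frac = 0.003),
    genome_len = 30000L,
    refdb = list(n_viral = 42L, n_cellular = 63L))
}

#' Compact project configuration for repeated validation runs
#'
#' A down-scaled variant of [default_project_config()]: three libraries at
#' 1.2e4 reads, two planted viruses (an ambigrammatic narna-like
#' index-hopping source at high abundance and a mitochondrial-code
#' mito-like virus), one index-hopped copy, a reagent contaminant shared
#' by two libraries, and an endogenous element in the third library.
#' Used where many independent projects must be generated and analysed
#' quickly (e.g. contamination-filter calibration across seeds).
#'
#' @return configuration list for [make_project()].
#' @export
compact_project_config <- function() {
  cfg <- default_project_config(n_libraries = 3L, depth = 12000L)
  cfg$n_host_transcripts <- 5L
  cfg$n_orphan_contigs <- 4L
  cfg$rrna_fracs <- c(0.45, 0.25)
  cfg$bacterial_libraries <- character(0)
  cfg$refdb <- list(n_viral = 12L, n_cellular = 20L)
  v <- function(name, arch, fam, div, lib, frac, status) {
    list(template = virus_template(name, arch, fam, div),
         library = lib, frac = frac, status = status)
  }
  cfg$viruses <- list(
    v("V01narna", "narna_single_orf_ambigrammatic", "Narnaviridae", 0.25,
      "L01", 0.1, "full"),
    v("V02mito", "mito_code_single_orf", "Mitoviridae", 0.30, "L02",
      0.005, "full"))
  cfg$hops <- list(list(source = "V01narna", source_library = "L01",
                        target_library = "L03", n_reads = 1L))
  cfg$reagent$prevalence <- 2L
  cfg$eve$library <- "L03"
  cfg
}

assemble_transcript <- function(prot_nt, utr = 45L) {
  paste0(utr_nt(utr), "TAA", prot_nt, "TAA", utr_nt(utr))
}

#' Generate a synthetic project directory with ground truth
#'
#' Builds the reference database, plants viruses, contaminants and an
#' endogenous viral element according to the configuration, draws reads
#' deterministically (per-element read counts are fixed, read positions
#' are seeded), and writes the project layout:
#' `refdb/`, `libraries/<lib>/contigs.fasta` + `reads.fasta`,
#' `host_genomes/<lib>.fasta`, `rbcl/<lib>.fasta`, `truth.tsv`,
#' `config.yaml`.  Rerunning with the same seed produces byte-identical
#' files.
#'
#' @param out_dir output directory (created).
#' @param seed integer master seed.
#' @param config see [default_project_config()].
#' @return invisibly, a list with `dir`, `truth` (data.frame), `config`,
#'   `seed`.
#' @export
make_project <- function(out_dir, seed, config = default_project_config()) {
  stopifnot(config$depth >= 1e4)
  libs <- sprintf("L%02d", seq_len(config$n_libraries))
  # construction guarantee: every index-hopped copy must land strictly
  # below 0.1 per cent of its source library's abundance
  for (h in config$hops) {
    src <- Filter(function(v) v$template$name == h$source, config$viruses)
    if (length(src) == 0) stop("hop source virus not in roster: ", h$source)
    src_reads <- round(src[[1]]$frac * config$depth)
    if (h$n_reads >= 0.001 * src_reads) {
      stop("hop copy of ", h$source, " would not fall below 0.1% of the ",
           "source abundance at this depth; raise depth or source frac")
    }
  }
  bad <- vapply(config$viruses, function(v) !(v$library %in% libs),
                logical(1))
  if (any(bad)) stop("virus assigned to a library absent from the project")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  db <- make_reference_db(derive_seed(seed, 1L), config$refdb$n_viral,
                          config$refdb$n_cellular,
                          out_dir = file.path(out_dir, "refdb"))
  genomes <- with_seed(derive_seed(seed, 2L), {
    setNames(lapply(libs, function(l) random_nt(config$genome_len)), libs)
  })
  viruses <- lapply(seq_along(config$viruses), function(vi) {
    spec <- config$viruses[[vi]]
    g <- make_viral_genome(spec$template, derive_seed(seed, 100L + vi), db)
    g$library <- spec$library; g$frac <- spec$frac; g$status <- spec$status
    g
  })
  names(viruses) <- vapply(viruses, `[[`, character(1), "name")
  reagent <- make_viral_genome(
    virus_template("REAGENT1", "narna_single_orf_ambigrammatic",
                   config$reagent$family, config$reagent$divergence),
    derive_seed(seed, 50L), db)
  eve <- make_viral_genome(
    virus_template("EVE1", "narna_single_orf_ambigrammatic",
                   config$eve$family, config$eve$divergence),
    derive_seed(seed, 60L), db)
  eve_seq <- unname(eve$segments[eve$rdrp_segment])
  # integrate the EVE into its host genome
  gl <- nchar(genomes[[config$eve$library]])
  at <- with_seed(derive_seed(seed, 61L), sample.int(gl - 1000L, 1))
  genomes[[config$eve$library]] <-
    paste0(substr(genomes[[config$eve$library]], 1, at), eve_seq,
           substr(genomes[[config$eve$library]], at + 1L, gl))
  dir.create(file.path(out_dir, "host_genomes"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "rbcl"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "libraries"), showWarnings = FALSE)
  truth <- list()
  for (li in seq_along(libs)) {
    lib <- libs[li]
    res <- with_seed(derive_seed(seed, 1000L + li), {
      build_library(lib, li, config, db, viruses, reagent, eve_seq, libs)
    })
    lib_dir <- file.path(out_dir, "libraries", lib)
    dir.create(lib_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(setNames(res$contigs$seq, res$contigs$id),
                file.path(lib_dir, "contigs.fasta"))
    writeLines(c(rbind(paste0(">", res$read_ids), res$reads)),
               file.path(lib_dir, "reads.fasta"))
    write_fasta(setNames(res$rbcl_ref, paste0(lib, "_rbcL_ref")),
                file.path(out_dir, "rbcl", paste0(lib, ".fasta")))
    write_fasta(setNames(genomes[[lib]], paste0(lib, "_genome")),
                file.path(out_dir, "host_genomes", paste0(lib, ".fasta")))
    truth[[li]] <- res$truth
  }
  truth <- do.call(rbind, truth)
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg_out <- config
  cfg_out$seed <- seed
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  invisible(list(dir = out_dir, truth = truth, config = config,
                 seed = seed))
}

# Assemble one library: contigs, deterministic per-element read counts,
# seeded read positions, and truth rows.
build_library <- function(lib, li, config, db, viruses, reagent, eve_seq,
                          libs) {
  phylum <- config$host_phyla[li]
  rl <- config$read_len
  pool <- db[db$kingdom == "Eukaryota" & db$phylum == phylum &
               db$family == "cellular", , drop = FALSE]
  pool <- pool[order(pool$id), , drop = FALSE]
  contigs <- list()
  truth <- list()
  add <- function(id, seq, type, count = NA_integer_, frac = NA_real_,
                  name = NA_character_, family = NA_character_,
                  template = NA_character_, divergence = NA_real_,
                  status = NA_character_, expected = "not_reported",
                  source_library = NA_character_) {
    contigs[[length(contigs) + 1L]] <<- list(id = id, seq = seq,
                                             count = count, frac = frac)
    truth[[length(truth) + 1L]] <<- data.frame(
      library_id = lib, contig_id = id, element_type = type, name = name,
      family = family, template = template, divergence = divergence,
      frac = frac, reads = count, genome_status = status,
      expected_outcome = expected, source_library = source_library,
      stringsAsFactors = FALSE)
  }
  for (k in 1:2) {
    add(sprintf("%s_rrna%d", lib, k), random_nt(config$rrna_lens[k]),
        "rrna", frac = config$rrna_fracs[k])
  }
  rbcl_row <- db[db$id == sprintf("rbcL_%s", phylum), ]
  rbcl_prot <- mutate_protein(rbcl_row$seq, 0.02)
  rbcl_seq <- assemble_transcript(reverse_translate(rbcl_prot))
  add(sprintf("%s_rbcl", lib), rbcl_seq, "rbcl", frac = config$rbcl_frac)
  for (t in seq_len(config$n_host_transcripts)) {
    src <- pool[((t - 1L) %% nrow(pool)) + 1L, ]
    prot <- mutate_protein(src$seq, config$host_divergence)
    add(sprintf("%s_host%02d", lib, t),
        assemble_transcript(reverse_translate(prot)), "host_transcript")
  }
  for (o in seq_len(config$n_orphan_contigs)) {
    add(sprintf("%s_orph%02d", lib, o), random_nt(config$orphan_len),
        "orphan", frac = config$orphan_frac_each)
  }
  if (lib %in% config$bacterial_libraries) {
    bpool <- db[db$kingdom == "Bacteria", , drop = FALSE]
    bpool <- bpool[order(bpool$id), , drop = FALSE]
    for (b in seq_len(config$n_bacterial_contigs)) {
      src <- bpool[((b - 1L) %% nrow(bpool)) + 1L, ]
      prot <- mutate_protein(src$seq, config$host_divergence)
      add(sprintf("%s_bact%02d", lib, b),
          assemble_transcript(reverse_translate(prot)),
          "bacterial_contaminant",
          frac = config$bacterial_frac_total / config$n_bacterial_contigs)
    }
  }
  for (v in viruses) {
    if (v$library != lib) next
    for (sn in names(v$segments)) {
      seq <- v$segments[[sn]]
      status <- v$status
      if (status == "partial" && sn == v$rdrp_segment) {
        cut <- v$rdrp_orf[1] + 3L * floor(0.3 * (v$rdrp_orf[2] -
                                                   v$rdrp_orf[1]) / 3)
        seq <- substr(seq, cut + 1L, nchar(seq))
      }
      add(sprintf("%s_%s", lib, sn), seq, "virus", frac = v$frac,
          name = v$name, family = v$family, template = v$architecture,
          divergence = v$realized_divergence,
          status = if (sn == v$rdrp_segment) status else NA_character_,
          expected = if (sn == v$rdrp_segment) "reported"
                     else "cp_segment")
    }
  }
  if (li <= config$reagent$prevalence) {
    add(sprintf("%s_reagent", lib),
        unname(reagent$segments[reagent$rdrp_segment]),
        "reagent_contaminant", frac = config$reagent$frac,
        name = "REAGENT1", family = config$reagent$family,
        expected = "filtered_reagent_contaminant")
  }
  if (lib == config$eve$library) {
    add(sprintf("%s_eve", lib), eve_seq, "eve", frac = config$eve$frac,
        name = "EVE1", family = config$eve$family,
        expected = "excluded_eve")
  }
  for (h in config$hops) {
    if (h$target_library != lib) next
    v <- viruses[[h$source]]
    add(sprintf("%s_hop_%s", lib, v$name),
        unname(v$segments[v$rdrp_segment]), "index_hop",
        count = h$n_reads, name = v$name, family = v$family,
        expected = "filtered_index_hopping",
        source_library = h$source_library)
  }
  # deterministic read counts: fixed fractions first, host transcripts
  # share the remainder equally
  ids <- vapply(contigs, `[[`, character(1), "id")
  seqs <- vapply(contigs, `[[`, character(1), "seq")
  fracs <- vapply(contigs, function(x) x$frac, numeric(1))
  counts <- vapply(contigs, function(x) x$count, numeric(1))
  counts[!is.na(fracs)] <- round(fracs[!is.na(fracs)] * config$depth)
  host_idx <- which(is.na(counts))
  remaining <- config$depth - sum(counts, na.rm = TRUE)
  stopifnot(remaining >= length(host_idx))
  base <- remaining %/% length(host_idx)
  counts[host_idx] <- base
  extra <- remaining - base * length(host_idx)
  if (extra > 0) counts[host_idx[seq_len(extra)]] <-
      counts[host_idx[seq_len(extra)]] + 1L
  counts <- as.integer(counts)
  stopifnot(sum(counts) == config$depth, all(nchar(seqs) >= rl))
  reads <- character(0)
  for (ci in seq_along(ids)) {
    n <- counts[ci]
    if (n == 0) next
    Lc <- nchar(seqs[ci])
    starts <- sample.int(Lc - rl + 1L, n, replace = TRUE)
    reads <- c(reads, substring(seqs[ci], starts, starts + rl - 1L))
  }
  read_ids <- sprintf("%s_r%06d", lib, seq_along(reads))
  truth <- do.call(rbind, truth)
  truth$reads <- counts[match(truth$contig_id, ids)]
  truth$rpm_truth <- truth$reads / config$depth * 1e6
  list(contigs = data.frame(id = ids, seq = seqs,
                            stringsAsFactors = FALSE),
       reads = reads, read_ids = read_ids, truth = truth,
       rbcl_ref = rbcl_seq)
}

#' Read a project directory
#'
#' @param dir project directory created by [make_project()] (or matching
#'   its layout).
#' @return list with `db`, `libraries` (named list of
#'   `list(contigs, reads, genome_path, rbcl_path)`), `truth` (or NULL),
#'   `dir`.
#' @export
read_project <- function(dir) {
  refdb_dir <- file.path(dir, "refdb")
  if (!dir.exists(refdb_dir)) stop("missing refdb/ in project directory")
  db <- read_reference_db(file.path(refdb_dir, "proteins.fasta"),
                          file.path(refdb_dir, "taxonomy.tsv"))
  lib_root <- file.path(dir, "libraries")
  lib_dirs <- if (dir.exists(lib_root)) {
    sort(list.dirs(lib_root, recursive = FALSE))
  } else character(0)
  libraries <- list()
  for (ld in lib_dirs) {
    lib <- basename(ld)
    seqs <- read_fasta(file.path(ld, "contigs.fasta"))
    reads <- read_fasta(file.path(ld, "reads.fasta"))
    gp <- file.path(dir, "host_genomes", paste0(lib, ".fasta"))
    rp <- file.path(dir, "rbcl", paste0(lib, ".fasta"))
    libraries[[lib]] <- list(
      contigs = data.frame(id = names(seqs), seq = unname(seqs),
                           stringsAsFactors = FALSE),
      reads = unname(reads),
      genome_path = if (file.exists(gp)) gp else NULL,
      rbcl_path = if (file.exists(rp)) rp else NULL)
  }
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path, stringsAsFactors = FALSE)
  } else NULL
  list(db = db, libraries = libraries, truth = truth, dir = dir)
}
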