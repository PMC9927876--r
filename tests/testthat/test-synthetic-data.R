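test_that("every synthetic RdRp carries the catalytic motifs at spacing", {
  db <- test_db()
  for (s in db$seq[db$is_rdrp]) {
    m <- find_motifs_abc(s)
    expect_false(is.na(m$motif_C_triad))
    expect_true(m$spacing_ok)
  }
  # family motif-C variety includes the non-canonical triads
  triads <- vapply(unique(db$family[db$is_rdrp]), function(f) {
    find_motifs_abc(db$seq[db$family == f & db$is_rdrp][1])$motif_C_triad
  }, character(1))
  expect_true(all(c("SDD", "IDD") %in% triads))
})

test_that("reverse-transcriptase-like decoys are rejected as viral", {
  db <- test_db()
  set.seed(401)
  decoys <- db[db$family == "retroelement", ]
  expect_gte(nrow(decoys), 1)
  expect_false(any(decoys$is_viral))
  for (i in seq_len(nrow(decoys))) {
    q <- mutate_protein(decoys$seq[i], 0.05)
    rc <- reciprocal_confirm(q, db)
    expect_equal(rc$status, "rejected_nonviral")
    # and their catalytic triads are disrupted by construction
    expect_true(is.na(find_motifs_abc(decoys$seq[i])$motif_C_triad))
  }
})

test_that("different seeds give disjoint sequences with identical schema", {
  d1 <- make_reference_db(1L, 12L, 12L)
  d2 <- make_reference_db(2L, 12L, 12L)
  expect_equal(names(d1), names(d2))
  expect_equal(d1$id, d2$id)
  expect_equal(length(intersect(d1$seq, d2$seq)), 0)
  d1b <- make_reference_db(1L, 12L, 12L)
  expect_equal(d1$seq, d1b$seq)
})

test_that("the mito template is code-dependent by construction", {
  db <- test_db()
  g <- make_viral_genome(
    virus_template("m1", "mito_code_single_orf", "Mitoviridae", 0.3),
    7L, db)
  seg <- g$segments[[g$rdrp_segment]]
  expect_equal(nrow(predict_orfs(seg, genetic_code("standard"), 200)), 0)
  mit <- predict_orfs(seg, genetic_code("mito"), 200)
  expect_true(g$protein %in% mit$protein)
  # the encoded ORF contains at least one internal TGA
  orf_nt <- substr(seg, g$rdrp_orf[1] + 1, g$rdrp_orf[2])
  codons <- substring(orf_nt, seq(1, nchar(orf_nt) - 2, 3),
                      seq(3, nchar(orf_nt), 3))
  expect_gte(sum(codons == "TGA"), 1)
})

test_that("the narna template is ambigrammatic", {
  db <- test_db()
  g <- make_viral_genome(
    virus_template("n1", "narna_single_orf_ambigrammatic",
                   "Narnaviridae", 0.25), 8L, db)
  seg <- g$segments[[g$rdrp_segment]]
  orfs <- predict_orfs(seg, min_aa_len = 200)
  orf <- orfs[orfs$protein == g$protein, ]
  expect_equal(nrow(orf), 1)
  expect_true(detect_ambigrammatic(orf, seg))
})

test_that("the partiti template emits two segments, RdRp plus CP", {
  db <- test_db()
  g <- make_viral_genome(
    virus_template("p1", "partiti_bisegmented", "Partitiviridae", 0.3),
    9L, db)
  expect_length(g$segments, 2)
  expect_equal(g$rdrp_segment, "p1_seg1")
  h <- search_protein(g$protein, db[db$is_rdrp, ])
  expect_gt(nrow(h), 0)
  # the CP segment encodes no RdRp
  cp_orfs <- predict_orfs(g$segments[["p1_seg2"]], min_aa_len = 200)
  for (p in cp_orfs$protein) {
    expect_equal(nrow(search_protein(p, db[db$is_rdrp, ])), 0)
  }
})

test_that("the toti template encodes CP 5-prime of the RdRp", {
  db <- test_db()
  g <- make_viral_genome(
    virus_template("t1", "toti_cp_rdrp", "Totiviridae", 0.3), 10L, db)
  seg <- g$segments[[g$rdrp_segment]]
  orfs <- predict_orfs(seg, min_aa_len = 200)
  orfs <- orfs[orfs$strand == "+", ]
  expect_gte(nrow(orfs), 2)
  rdrp_start <- orfs$start[orfs$protein == g$protein]
  cp_start <- min(orfs$start[orfs$protein != g$protein])
  expect_lt(cp_start, rdrp_start)
})

test_that("realized divergence stays within 5 points of target", {
  db <- test_db()
  set.seed(411)
  for (r in 1:50) {
    target <- runif(1, 0.1, 0.6)
    g <- make_viral_genome(
      virus_template("d1", "marna_polyprotein", "Marnaviridae", target),
      1000L + r, db)
    expect_lt(abs(g$realized_divergence - target), 0.05)
  }
  expect_error(virus_template("bad", "marna_polyprotein", "Marnaviridae",
                              0.75))
})

test_that("compact projects have the declared layout and ground truth", {
  dir <- tempfile("proj")
  p <- make_project(dir, seed = 5L, config = compact_project_config())
  expect_true(file.exists(file.path(dir, "refdb", "proteins.fasta")))
  expect_true(file.exists(file.path(dir, "refdb", "taxonomy.tsv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  libs <- list.dirs(file.path(dir, "libraries"), recursive = FALSE)
  expect_length(libs, 3)
  for (ld in libs) {
    lib <- basename(ld)
    expect_true(file.exists(file.path(ld, "contigs.fasta")))
    expect_true(file.exists(file.path(ld, "reads.fasta")))
    expect_true(file.exists(file.path(dir, "host_genomes",
                                      paste0(lib, ".fasta"))))
    # per-library read counts conserve the configured depth
    reads <- read_fasta(file.path(ld, "reads.fasta"))
    expect_equal(length(reads), 12000L)
    tr <- p$truth[p$truth$library_id == lib, ]
    expect_equal(sum(tr$reads), 12000L)
  }
  unlink(dir, recursive = TRUE)
})

test_that("planted abundances reproduce from the emitted reads", {
  dir <- tempfile("proj")
  p <- make_project(dir, seed = 6L, config = compact_project_config())
  pr <- read_project(dir)
  for (lib in names(pr$libraries)) {
    contigs <- pr$libraries[[lib]]$contigs
    mp <- map_reads(pr$libraries[[lib]]$reads,
                    setNames(contigs$seq, contigs$id), k = 25)
    expect_equal(sum(mp$counts) + mp$unassigned, mp$total)
    tr <- p$truth[p$truth$library_id == lib, ]
    # rpm of the planted virus within sampling tolerance of truth
    vir <- tr[tr$element_type == "virus", ]
    for (i in seq_len(nrow(vir))) {
      got_rpm <- reads_per_million(mp$counts[[vir$contig_id[i]]],
                                   mp$total)
      expect_equal(got_rpm, vir$rpm_truth[i], tolerance = 0.2)
    }
  }
  unlink(dir, recursive = TRUE)
})

test_that("index-hopped copies sit below 0.1% of source abundance", {
  dir <- tempfile("proj")
  p <- make_project(dir, seed = 7L, config = compact_project_config())
  tr <- p$truth
  hops <- tr[tr$element_type == "index_hop", ]
  expect_gte(nrow(hops), 1)
  for (i in seq_len(nrow(hops))) {
    src <- tr[tr$library_id == hops$source_library[i] &
                tr$name == hops$name[i] & tr$element_type == "virus", ]
    expect_lt(hops$rpm_truth[i], 0.001 * max(src$rpm_truth))
  }
  # inconsistent configs are refused outright
  bad <- compact_project_config()
  bad$hops[[1]]$n_reads <- 100L
  expect_error(make_project(tempfile(), seed = 1L, config = bad),
               "0.1%")
  bad2 <- compact_project_config()
  bad2$viruses[[1]]$library <- "L99"
  expect_error(make_project(tempfile(), seed = 1L, config = bad2),
               "absent")
  unlink(dir, recursive = TRUE)
})

test_that("projects are byte-identical across reruns of the same seed", {
  d1 <- tempfile("pa"); d2 <- tempfile("pb"); d3 <- tempfile("pc")
  make_project(d1, seed = 9L, config = compact_project_config())
  make_project(d2, seed = 9L, config = compact_project_config())
  make_project(d3, seed = 10L, config = compact_project_config())
  files <- list.files(d1, recursive = TRUE)
  expect_equal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                     tools::md5sum(file.path(d2, f))[[1]])
  }
  # a different seed changes the sequence content
  expect_false(identical(
    tools::md5sum(file.path(d1, "refdb", "proteins.fasta"))[[1]],
    tools::md5sum(file.path(d3, "refdb", "proteins.fasta"))[[1]]))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("planted RdRps at moderate divergence are always detectable", {
  db <- test_db()
  set.seed(421)
  for (r in 1:10) {
    fam <- sample(unique(db$family[db$is_rdrp]), 1)
    src <- db$seq[db$family == fam & db$is_rdrp][1]
    q <- mutate_protein(src, runif(1, 0.05, 0.40))
    h <- search_protein(q, db, evalue_cutoff = 1e-3)
    expect_gt(nrow(h), 0)
    expect_lte(h$evalue[1], 1e-3)
  }
})
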