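test_that("self-alignment scores the matrix diagonal at 100% identity", {
  m <- blosum62_matrix()
  p <- "MKVLWAALLVTFLAGCQA"
  al <- local_align(p, p)
  chars <- strsplit(p, "")[[1]]
  expect_equal(al$raw_score, sum(m[cbind(chars, chars)]))
  expect_equal(al$pct_identity, 100)
  expect_equal(al$query_span, c(0L, nchar(p)))
})

test_that("all-negative pairs give score zero and an empty alignment", {
  al <- local_align("CC", "WW")  # C/W scores -2 under BLOSUM62
  expect_equal(al$raw_score, 0)
  expect_equal(al$aln_len, 0)
  expect_equal(al$q_aln, "")
})

test_that("alignment scores equal independent dynamic-programming oracles", {
  m <- blosum62_matrix()
  set.seed(71)
  # small hand-rolled R DP oracle validates the recursion itself
  for (r in 1:12) {
    a <- rand_prot(sample(5:40, 1))
    b <- rand_prot(sample(5:40, 1))
    expect_equal(local_score(a, b), sw_oracle_r(a, b, m, 11, 1))
  }
  # larger-scale agreement with the Biostrings aligner
  for (r in 1:60) {
    a <- rand_prot(sample(10:300, 1))
    b <- rand_prot(sample(10:300, 1))
    expect_equal(local_score(a, b), sw_oracle_biostrings(a, b, m, 11, 1))
  }
})

test_that("alignment score is symmetric", {
  set.seed(81)
  for (r in 1:10) {
    a <- rand_prot(60); b <- rand_prot(80)
    expect_equal(local_score(a, b), local_score(b, a))
  }
})

test_that("unknown residues are neutral", {
  # X against anything scores 0 and never breaks an alignment
  expect_equal(local_score("AAXAA", "AAJAA"), local_score("AAXAA", "AAXAA"))
})

test_that("E-values follow the closed form and its monotonicities", {
  p <- aa_karlin_params()
  for (s in seq(20, 200, by = 20)) {
    expect_equal(estimate_evalue(s, 200, 1e5),
                 0.041 * 200 * 1e5 * exp(-0.267 * s))
  }
  expect_equal(estimate_evalue(50, 200, 2e5) / estimate_evalue(50, 200, 1e5),
               2)
  ev <- estimate_evalue(seq(10, 300, by = 10), 200, 1e5)
  expect_true(all(diff(ev) < 0))
  expect_lt(estimate_evalue(1e4, 200, 1e5), 1e-300 * 1)
  expect_true(all(diff(bit_score(c(10, 50, 100))) > 0))
})

test_that("best-hit search finds the identical protein and nothing else", {
  db <- test_db()
  q <- db$seq[5]
  h <- search_protein(q, db, max_targets = 1L)
  expect_equal(h$target_id, db$id[5])
  expect_equal(h$pct_identity, 100)
  set.seed(91)
  # an unrelated random peptide finds nothing at the cutoff
  h0 <- search_protein(rand_prot(40), db)
  expect_equal(nrow(h0), 0)
})

test_that("seeded search returns exactly the exhaustive hit set", {
  db <- test_db()
  set.seed(101)
  queries <- c(
    vapply(sample(seq_len(nrow(db)), 6), function(i) {
      mutate_protein(db$seq[i], 0.35)
    }, character(1)),
    vapply(1:4, function(i) rand_prot(300), character(1)))
  for (q in queries) {
    hs <- search_protein(q, db, max_targets = 50L, mode = "seeded")
    he <- search_protein(q, db, max_targets = 50L, mode = "exhaustive")
    expect_equal(hs, he)
  }
})

test_that("unrelated decoys never change the best hit, only its E-value", {
  db <- test_db()
  set.seed(111)
  q <- mutate_protein(db$seq[db$is_rdrp][1], 0.3)
  h1 <- search_protein(q, db)
  decoys <- data.frame(id = sprintf("zz_decoy_%02d", 1:10),
                       seq = vapply(1:10, function(i) rand_prot(300), ""),
                       kingdom = "Eukaryota", phylum = "none",
                       family = "none", species = "none",
                       is_viral = FALSE, is_rdrp = FALSE,
                       stringsAsFactors = FALSE)
  h2 <- search_protein(q, rbind(db, decoys))
  expect_equal(h2$target_id, h1$target_id)
  expect_equal(h2$raw_score, h1$raw_score)
  expect_gt(h2$evalue, h1$evalue)
})

test_that("translated search recovers fragments below the ORF floor", {
  db <- test_db()
  rdrp_db <- db[db$is_rdrp, ]
  set.seed(121)
  frag <- substr(rdrp_db$seq[2], 101, 250)  # 150 aa, below the 200-aa floor
  frag_nt <- rdrpscout:::reverse_translate(frag)
  contig <- paste0(rand_nt(150), "TAA", frag_nt, "TAA", rand_nt(150))
  expect_equal(nrow(predict_orfs(contig, min_aa_len = 200)), 0)
  h <- search_translated(contig, rdrp_db, contig_id = "frag")
  expect_equal(nrow(h), 1)
  expect_equal(h$target_id, rdrp_db$id[2])
  expect_lte(h$evalue, 1e-3)
  # a random contig yields no hit at the cutoff
  h0 <- search_translated(rand_nt(600), rdrp_db)
  expect_equal(nrow(h0), 0)
})

test_that("translated search agrees with frame-wise protein search", {
  db <- test_db()
  rdrp_db <- db[db$is_rdrp, ]
  set.seed(131)
  for (r in 1:5) {
    src <- sample(seq_len(nrow(rdrp_db)), 1)
    prot <- mutate_protein(rdrp_db$seq[src], 0.3)
    contig <- paste0(rand_nt(60), "TAA",
                     rdrpscout:::reverse_translate(prot), "TAA",
                     rand_nt(60))
    h <- search_translated(contig, rdrp_db, contig_id = "c")
    frames <- six_frame_translations(contig)
    best <- NULL
    for (nm in names(frames)) {
      hf <- search_protein(frames[[nm]], rdrp_db, query_id = "c")
      if (nrow(hf) == 0) next
      if (is.null(best) || hf$bitscore > best$bitscore) best <- hf
    }
    expect_equal(h$target_id, best$target_id)
    expect_equal(h$raw_score, best$raw_score)
  }
})

test_that("reciprocal confirmation separates viral from cellular origins", {
  db <- test_db()
  set.seed(141)
  viral_q <- mutate_protein(db$seq[db$is_rdrp][3], 0.25)
  expect_equal(reciprocal_confirm(viral_q, db)$status, "confirmed")
  cell_idx <- which(!db$is_viral & db$family == "cellular")[1]
  host_q <- mutate_protein(db$seq[cell_idx], 0.1)
  expect_equal(reciprocal_confirm(host_q, db)$status, "rejected_nonviral")
  expect_equal(reciprocal_confirm(rand_prot(50), db)$status, "no_hit")
})

test_that("exact bitscore ties are resolved by target id", {
  set.seed(151)
  shared <- rand_prot(120)
  tie_db <- data.frame(
    id = c("A_cellular", "B_viral"), seq = c(shared, shared),
    kingdom = c("Eukaryota", "Viruses"), phylum = c("x", "y"),
    family = c("cellular", "Totiviridae"),
    species = c("sp1", "sp2"), is_viral = c(FALSE, TRUE),
    is_rdrp = c(FALSE, TRUE), stringsAsFactors = FALSE)
  rc <- reciprocal_confirm(shared, tie_db)
  expect_equal(rc$best_hit$target_id, "A_cellular")
  expect_equal(rc$status, "rejected_nonviral")
  # swapping ids flips the deterministic winner
  tie_db$id <- c("B_cellular", "A_viral")
  rc2 <- reciprocal_confirm(shared, tie_db)
  expect_equal(rc2$best_hit$target_id, "A_viral")
  expect_equal(rc2$status, "confirmed")
})

test_that("nearest-reference classification tracks the source family", {
  db <- test_db()
  set.seed(161)
  toti <- db[db$family == "Totiviridae" & db$is_rdrp, ][1, ]
  q <- mutate_protein(toti$seq, 0.3)
  cls <- classify_nearest_reference(q, db)
  expect_equal(cls$family, "Totiviridae")
  # identity decreases monotonically with simulated divergence
  pid <- vapply(c(0, 0.2, 0.4, 0.6), function(d) {
    classify_nearest_reference(mutate_protein(toti$seq, d),
                               db)$pct_identity
  }, numeric(1))
  expect_true(all(diff(pid) < 0))
  expect_equal(pid[1], 100)
})

test_that("hit tables are written in 12-column tabular form", {
  db <- test_db()
  h <- search_protein(db$seq[3], db, query_id = "q1")
  path <- tempfile(fileext = ".tsv")
  write_hit_table(h, path)
  tab <- utils::read.delim(path, header = FALSE)
  expect_equal(ncol(tab), 12)
  expect_equal(tab$V1, "q1")
  expect_equal(tab$V7, 1)  # 1-based qstart on write
  unlink(path)
})
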