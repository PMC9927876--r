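test_that("read mapping assigns error-free reads and conserves totals", {
  set.seed(201)
  ref <- rand_nt(2000)
  reads <- substring(ref, sample(1:1901, 1000, replace = TRUE),
                     sample(1:1901, 1000, replace = TRUE) + 99)
  starts <- sample(1:1901, 1000, replace = TRUE)
  reads <- substring(ref, starts, starts + 99)
  mp <- map_reads(reads, c(refA = ref), k = 25)
  expect_equal(unname(mp$counts["refA"]), 1000L)
  expect_equal(mp$unassigned, 0L)

  # reads sharing no k-mer with any reference stay unassigned
  alien <- vapply(1:50, function(i) rand_nt(100), character(1))
  mp2 <- map_reads(alien, c(refA = ref), k = 25)
  expect_equal(sum(mp2$counts), 0L)
  expect_equal(mp2$unassigned, 50L)
  expect_equal(sum(mp2$counts) + mp2$unassigned, mp2$total)
})

test_that("read mapping equals an exact substring-search oracle", {
  set.seed(211)
  refs <- setNames(vapply(1:10, function(i) rand_nt(sample(500:1500, 1)),
                          character(1)),
                   sprintf("c%02d", sample(10)))
  read_from <- sample(names(refs), 800, replace = TRUE)
  reads <- vapply(read_from, function(rn) {
    s <- sample(nchar(refs[[rn]]) - 99, 1)
    substr(refs[[rn]], s, s + 99)
  }, character(1))
  reads <- c(reads, vapply(1:100, function(i) rand_nt(100), character(1)))
  mp <- map_reads(reads, refs, k = 25)
  # oracle: lexicographically first reference containing the read verbatim
  oracle_counts <- setNames(integer(length(refs)), names(refs))
  una <- 0L
  ord <- sort(names(refs))
  for (rd in reads) {
    hit <- NA_character_
    for (rn in ord) {
      if (grepl(rd, refs[[rn]], fixed = TRUE)) { hit <- rn; break }
    }
    if (is.na(hit)) una <- una + 1L else
      oracle_counts[hit] <- oracle_counts[hit] + 1L
  }
  expect_equal(mp$counts, oracle_counts)
  expect_equal(mp$unassigned, una)
  expect_equal(sum(mp$counts) + mp$unassigned, length(reads))
})

test_that("reads per million is the stated ratio", {
  expect_equal(reads_per_million(10, 1e6), 10)
  expect_equal(reads_per_million(0, 5000), 0)
  expect_equal(reads_per_million(48, 1e6), 48)
  expect_error(reads_per_million(1, 0), "positive")
})

test_that("TPM normalises length-corrected counts to one million", {
  tpm <- tpm_from_counts(c(100, 100, 800), c(1000, 2000, 4000))
  expect_equal(sum(tpm), 1e6)
  # the length-normalised rates are 0.1, 0.05, 0.2
  expect_equal(tpm, c(0.1, 0.05, 0.2) / 0.35 * 1e6)
  expect_equal(tpm_from_counts(c(0, 0), c(100, 100)), c(0, 0))
})

test_that("the cross-library filter applies the strict 0.1% rule", {
  ab <- data.frame(contig_id = c("x", "x"), library_id = c("A", "B"),
                   rpm = c(1000, 0.5))
  fl <- cross_library_filter(ab)
  expect_equal(fl$flag, c("pass", "index_hopping"))

  # boundary: exactly 0.1% of the maximum passes (strict less-than)
  ab2 <- data.frame(contig_id = c("x", "x"), library_id = c("A", "B"),
                    rpm = c(1000, 1.0))
  expect_equal(cross_library_filter(ab2)$flag, c("pass", "pass"))

  # single-library clusters always pass
  ab3 <- data.frame(contig_id = "x", library_id = "A", rpm = 3)
  expect_equal(cross_library_filter(ab3)$flag, "pass")
})

test_that("the cross-library filter is idempotent and order-independent", {
  set.seed(221)
  ab <- data.frame(contig_id = "x", library_id = LETTERS[1:6],
                   rpm = c(5000, 2, 900, 4.9, 0.1, 5.1))
  f1 <- cross_library_filter(ab)
  f2 <- cross_library_filter(f1[, names(ab)])
  expect_equal(f1$flag, f2$flag)
  perm <- sample(6)
  f3 <- cross_library_filter(ab[perm, ])
  expect_equal(f3$flag, f1$flag[perm])
  expect_equal(f1$flag,
               c("pass", "index_hopping", "pass", "index_hopping",
                 "index_hopping", "pass"))
})

test_that("the ubiquity rule flags identical high-prevalence sequences", {
  expect_equal(ubiquity_contaminant_filter(100, 86, 570),
               "reagent_contaminant")
  expect_equal(ubiquity_contaminant_filter(100, 2, 570), "pass")
  # near-identical sequences are not reagent contaminants under the
  # 100%-identity rule, whatever their prevalence
  expect_equal(ubiquity_contaminant_filter(99.5, 200, 570), "pass")
  # sensitivity to the identity threshold: the same prevalence flips the
  # verdict only at exact identity
  for (ident in c(90, 95, 99, 99.9)) {
    expect_equal(ubiquity_contaminant_filter(ident, 200, 570), "pass")
  }
  expect_equal(ubiquity_contaminant_filter(100, 200, 570),
               "reagent_contaminant")
})

test_that("greedy extension recovers a genome from tiling reads", {
  set.seed(231)
  genome <- rand_nt(1500)
  starts <- seq(1, 1401, by = 10)
  reads <- substring(genome, starts, starts + 99)
  contig <- substr(genome, 151, 1350)  # middle 80%
  ext <- extend_contig(contig, reads, min_overlap = 31)
  expect_equal(ext, genome)
  expect_true(grepl(contig, ext, fixed = TRUE))
})

test_that("extension is inert without overlapping reads", {
  set.seed(241)
  contig <- rand_nt(500)
  reads <- vapply(1:50, function(i) rand_nt(100), character(1))
  expect_equal(extend_contig(contig, reads), contig)
})

test_that("a single overlapping read extends by exactly its overhang", {
  set.seed(251)
  genome <- rand_nt(400)
  contig <- substr(genome, 1, 330)
  read <- substr(genome, 301, 400)  # 30 nt overlap is below the floor
  expect_equal(extend_contig(contig, read, min_overlap = 31), contig)
  read2 <- substr(genome, 300, 399)  # 31 nt overlap
  ext <- extend_contig(contig, read2, min_overlap = 31, max_rounds = 1)
  expect_equal(ext, substr(genome, 1, 399))
})

test_that("conflicting overhang consensus stops extension at the tie", {
  base <- strrep("ACGT", 30)         # 120 nt contig
  r1 <- paste0(substr(base, 90, 120), "AAAA")
  r2 <- paste0(substr(base, 90, 120), "TTTT")
  ext <- extend_contig(base, c(r1, r2), min_overlap = 31)
  expect_equal(ext, base)
  # agreeing first position, conflicting second
  r3 <- paste0(substr(base, 90, 120), "GAAA")
  r4 <- paste0(substr(base, 90, 120), "GTTT")
  ext2 <- extend_contig(base, c(r3, r4), min_overlap = 31)
  expect_equal(ext2, paste0(base, "G"))
})

test_that("rbcL comparison classifies abundance ratios", {
  expect_equal(rbcl_comparison(50, 40)$magnitude_class,
               "comparable_or_higher")
  expect_equal(rbcl_comparison(1, 1000)$magnitude_class, "lower")
  eq <- rbcl_comparison(120, 120)
  expect_equal(eq$ratio, 1)
  expect_equal(eq$magnitude_class, "comparable_or_higher")
  expect_equal(rbcl_comparison(10, NA)$magnitude_class, "not_assessed")
})

test_that("candidate clustering groups near-identical sequences", {
  set.seed(261)
  a <- rand_nt(1000)
  b <- a
  substr(b, 500, 500) <- if (substr(a, 500, 500) == "A") "C" else "A"
  c2 <- rand_nt(1000)
  cl <- cluster_candidate_sequences(c(a, b, c2))
  expect_equal(cl[1], cl[2])   # 99.9% identical
  expect_false(cl[1] == cl[3])
  # short fragment of a: coverage below 90% keeps it apart
  frag <- substr(a, 1, 500)
  cl2 <- cluster_candidate_sequences(c(a, frag))
  expect_false(cl2[1] == cl2[2])
})
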