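test_that("profile scores match the closed-form log-odds on a toy alignment", {
  aln <- c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGWIKL")
  pf <- build_profile(aln, pseudocount = 0.5)
  expect_equal(pf$length, 10)
  bg <- 1 / 20
  # column 7: H twice, W once, N = 3, pc = 0.5
  expect_equal(unname(pf$log_odds[7, "H"]),
               log((2 + 0.5 * bg) / ((3 + 0.5) * bg)))
  expect_equal(unname(pf$log_odds[7, "W"]),
               log((1 + 0.5 * bg) / ((3 + 0.5) * bg)))
  expect_equal(unname(pf$log_odds[7, "A"]),
               log((0 + 0.5 * bg) / ((3 + 0.5) * bg)))
  # observed consensus scores positive, unobserved residues negative
  expect_gt(pf$log_odds[1, "A"], 0)
  expect_lt(pf$log_odds[1, "C"], pf$log_odds[1, "A"])
  expect_lt(pf$log_odds[1, "W"], 0)
})

test_that("identical sequences give a consensus-maximal profile", {
  seqs <- rep("MKDDYSKFDQWW", 5)
  pf <- build_profile(seqs)
  expect_equal(pf$consensus, "MKDDYSKFDQWW")
  for (j in seq_len(pf$length)) {
    expect_equal(names(which.max(pf$log_odds[j, ])),
                 substr("MKDDYSKFDQWW", j, j))
  }
})

test_that("majority-gap columns are dropped and ragged input refused", {
  seqs <- c("AC-DEFGHIKLM", "AC-DEFGHIKLM", "ACWDEFGHIKLM",
            "AC-DEFGHIKLM")
  pf <- build_profile(seqs)
  expect_equal(pf$length, 11)  # the 75%-gap column is removed
  expect_error(build_profile(c("ACD", "AC", "ACD")), "ragged")
})

test_that("profile scanning separates planted signal from shuffles", {
  db <- test_db()
  profs <- rdrp_profiles(db)
  pf <- profs[[1]]
  fam <- names(profs)[1]
  member <- db$seq[db$family == fam & db$is_rdrp][1]
  sc <- scan_profile(member, pf, n_shuffles = 100, seed = 5)
  expect_true(sc$scanned)
  expect_lt(sc$empirical_evalue, 1e-6)
  # shuffled protein: E-value near 1
  set.seed(6)
  shuf <- paste(sample(strsplit(member, "")[[1]]), collapse = "")
  sc0 <- scan_profile(shuf, pf, n_shuffles = 100, seed = 5)
  expect_gt(sc0$empirical_evalue, 0.01)
  # shorter protein than profile: no scan
  expect_false(scan_profile("MKV", pf, n_shuffles = 10, seed = 1)$scanned)
})

test_that("profile scan E-values are reproducible bit for bit", {
  db <- test_db()
  pf <- rdrp_profiles(db)[[2]]
  set.seed(7)
  p <- rand_prot(300)
  a <- scan_profile(p, pf, n_shuffles = 150, seed = 42)
  b <- scan_profile(p, pf, n_shuffles = 150, seed = 42)
  expect_identical(a, b)
  c2 <- scan_profile(p, pf, n_shuffles = 150, seed = 43)
  expect_false(identical(a$empirical_evalue, c2$empirical_evalue))
})

test_that("a 30%-diverged RdRp is detected by its family profile", {
  db <- test_db()
  profs <- rdrp_profiles(db)
  set.seed(8)
  hits <- 0L
  n <- 30L
  for (r in seq_len(n)) {
    fam <- sample(names(profs), 1)
    src <- db$seq[db$family == fam & db$is_rdrp][1]
    div <- mutate_protein(src, 0.30)
    sc <- scan_profile(div, profs[[fam]], n_shuffles = 200, seed = 100 + r)
    if (sc$empirical_evalue < 1e-5) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("catalytic motif detection follows the configured patterns", {
  set.seed(9)
  backbone <- function(triad, a_at = 100, c_at = 210) {
    p <- rdrpscout:::scrub_triads(rand_prot(400))
    substr(p, a_at + 1, a_at + 6) <- "DYSKFD"
    substr(p, a_at + 31, a_at + 34) <- "GAMS"
    substr(p, c_at + 1, c_at + 3) <- triad
    rdrpscout:::scrub_triads(p, keep_at = c_at, region_end = c_at)
  }
  for (triad in c("GDD", "SDD", "IDD", "ADD", "GDN")) {
    m <- find_motifs_abc(backbone(triad))
    expect_equal(m$motif_C_triad, triad)
    expect_true(m$has_A)
    expect_true(m$spacing_ok)
    expect_equal(m$positions$C, 210)
  }
  # GDT is not a valid motif C
  m <- find_motifs_abc(backbone("GDT"))
  expect_true(is.na(m$motif_C_triad))
  expect_false(m$spacing_ok)
})

test_that("motif positions agree with a regex oracle on the fixture", {
  set.seed(10)
  p <- rdrpscout:::scrub_triads(rand_prot(400))
  substr(p, 101, 106) <- "DYSKFD"
  substr(p, 131, 134) <- "GAMS"
  substr(p, 211, 213) <- "GDD"
  p <- rdrpscout:::scrub_triads(p, keep_at = 210, region_end = 210)
  m <- find_motifs_abc(p)
  expect_equal(m$positions$C, as.integer(regexpr("[GSAI]D[DN]", p)) - 1L)
  expect_equal(m$positions$C, 210)
  expect_true(m$has_A)
  expect_equal(m$positions$A, 100)
  expect_true(m$spacing_ok)  # A->C separation 110, inside [50, 300]
})

test_that("A-C spacing outside the window fails spacing_ok", {
  # the only A motif sits 20 residues upstream of C: too close
  p <- paste0(strrep("K", 190), "DYSKFD", strrep("K", 14), "GDD",
              strrep("K", 100))
  m <- find_motifs_abc(p)
  expect_equal(m$positions$C, 210)
  expect_true(m$has_A)
  expect_equal(m$positions$A, 190)
  expect_false(m$spacing_ok)
})

test_that("curation resolves representative borderline cases", {
  mC_idd <- list(motif_C_triad = "IDD", spacing_ok = TRUE)
  mC_none <- list(motif_C_triad = NA_character_, spacing_ok = FALSE)
  # strong profile hit with weak structure support: retained
  expect_equal(curate_candidate(8.7e-06, 40.7, NA, mC_idd)$verdict,
               "retained")
  # confident non-viral structure assignment: discarded
  expect_equal(curate_candidate(5e-04, 95, FALSE, mC_idd)$verdict,
               "discarded_nonviral")
  # grey-zone e-value, no usable triad (GDT case): uncertain
  expect_equal(curate_candidate(4.6e-05, 56.7, NA, mC_none)$verdict,
               "uncertain")
})

test_that("the curation decision grid matches its documented truth table", {
  evs <- c(1e-6, 1e-5, 5e-5, 1e-3, 5e-3)
  confs <- c(NA, 50, 95)
  virals <- c(NA, TRUE, FALSE)
  motifs <- list(good = list(motif_C_triad = "GDD", spacing_ok = TRUE),
                 none = list(motif_C_triad = NA_character_,
                             spacing_ok = FALSE))
  # independent restatement of the rule
  expected_verdict <- function(ev, conf, viral, motif_ok) {
    conf_high <- !is.na(conf) && conf > 90
    if (conf_high && isFALSE(viral)) return("discarded_nonviral")
    if (ev <= 1e-5) return("retained")
    if (conf_high && isTRUE(viral)) return("retained")
    if (ev > 1e-3) return("discarded_weak")
    if (motif_ok) return("retained")
    "uncertain"
  }
  for (ev in evs) for (conf in confs) for (viral in virals)
    for (mn in names(motifs)) {
      got <- curate_candidate(ev, conf, viral, motifs[[mn]])$verdict
      want <- expected_verdict(ev, conf, viral, mn == "good")
      expect_equal(got, want,
                   info = sprintf("ev=%g conf=%s viral=%s motif=%s",
                                  ev, conf, viral, mn))
    }
})
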