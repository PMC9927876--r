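#' Build a position-specific scoring matrix from a seed alignment
#'
#' Per-column log-odds scores against a background amino-acid frequency
#' vector, with a pseudocount:
#' `score(col, aa) = log((count + pc * bg_aa) / ((N + pc) * bg_aa))`
#' where `count` is the residue count in the column, `N` the number of
#' non-gap residues in the column and `pc` the pseudocount mass.  Columns
#' with more than 50 per cent gaps are dropped.
#'
#' @param aligned_seqs character vector (>= 3) of equal-length gapped
#'   amino-acid strings (gap symbol `-`).
#' @param pseudocount positive pseudocount mass (default 1).
#' @param background named numeric vector of residue frequencies summing
#'   to 1; default uniform over the 20 standard residues.
#' @param name profile name.
#' @return list of class `rdrp_profile` with `name`, `length`,
#'   `log_odds` (columns x residues matrix), `background`, `consensus`.
#' @export
build_profile <- function(aligned_seqs, pseudocount = 1,
                          background = NULL, name = "profile") {
  stopifnot(length(aligned_seqs) >= 3, pseudocount > 0)
  widths <- nchar(aligned_seqs)
  if (length(unique(widths)) != 1) stop("ragged alignment")
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), aa20)
  }
  stopifnot(abs(sum(background) - 1) < 1e-8)
  mat <- do.call(rbind, strsplit(aligned_seqs, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= 0.5
  mat <- mat[, keep, drop = FALSE]
  L <- ncol(mat)
  if (L < 10) stop("profile too short after gap-column removal")
  lo <- matrix(0, L, length(aa20), dimnames = list(NULL, aa20))
  consensus <- character(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col != "-"]
    n <- length(col)
    cnt <- table(factor(col, levels = aa20))
    lo[j, ] <- log((as.numeric(cnt) + pseudocount * background[aa20]) /
                     ((n + pseudocount) * background[aa20]))
    consensus[j] <- aa20[which.max(lo[j, ])]
  }
  structure(list(name = name, length = L, log_odds = lo,
                 background = background,
                 consensus = paste(consensus, collapse = "")),
            class = "rdrp_profile")
}

#' Scan a protein with a profile and compute an empirical E-value
#'
#' The best ungapped window score of the profile over all offsets is
#' compared to a null distribution obtained by residue-shuffling the
#' protein `n_shuffles` times and refitting a Gumbel (location-scale) law
#' to the null best-window scores by the method of moments.  The upper
#' tail probability of the observed score is scaled by `db_size` to give
#' an E-value on the scale of the profile database searched.  Results are
#' reproducible bit for bit given (`seed`, `n_shuffles`).
#'
#' @param protein amino-acid string; must be at least as long as the
#'   profile.
#' @param profile an `rdrp_profile` from [build_profile()].
#' @param n_shuffles number of residue shuffles for the null (default 200).
#' @param seed integer seed (required for reproducibility).
#' @param db_size number of profiles in the database being scanned
#'   (scales the per-profile p-value to an expectation; default 1).
#' @return list with `best_score`, `empirical_evalue`, `offset` (0-based
#'   offset of the best window) and `scanned` (FALSE when the protein is
#'   shorter than the profile).
#' @export
scan_profile <- function(protein, profile, n_shuffles = 200L, seed,
                         db_size = 1) {
  stopifnot(inherits(profile, "rdrp_profile"))
  if (nchar(protein) < profile$length) {
    return(list(best_score = NA_real_, empirical_evalue = NA_real_,
                offset = NA_integer_, scanned = FALSE))
  }
  best <- c_pssm_best_batch(protein, profile$log_odds)[1]
  off <- c_pssm_best_offset(protein, profile$log_odds)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  null_scores <- with_seed(seed, {
    shuffled <- vapply(seq_len(n_shuffles), function(i) {
      paste(sample(chars), collapse = "")
    }, character(1))
    c_pssm_best_batch(shuffled, profile$log_odds)
  })
  mu_sd <- c(mean(null_scores), sd(null_scores))
  if (!is.finite(mu_sd[2]) || mu_sd[2] <= 0) {
    # degenerate null (e.g. single-symbol protein): rank-based fallback
    p <- (sum(null_scores >= best) + 1) / (n_shuffles + 1)
    return(list(best_score = best, empirical_evalue = p * db_size,
                offset = off, scanned = TRUE))
  }
  beta <- mu_sd[2] * sqrt(6) / pi
  mu <- mu_sd[1] - 0.5772156649 * beta
  z <- (best - mu) / beta
  p <- -expm1(-exp(-z))          # Gumbel upper tail, accurate for small p
  p <- min(max(p, 1e-300), 1)
  list(best_score = best, empirical_evalue = p * db_size, offset = off,
       scanned = TRUE)
}

#' Motif configuration for catalytic A/B/C detection
#'
#' Defaults: motif C is the first triad matching `[GSAI]D[DN]`; motif A is
#' `D-x(4,5)-D` upstream of C; motif B is `G-x(1,3)-[ST]` between A and C;
#' spacing is acceptable when the A-to-C separation lies in 50--300
#' residues.  All patterns and windows are configuration, not code.
#'
#' @param c_pattern,a_pattern,b_pattern regular expressions.
#' @param ac_min,ac_max allowed A-to-C separation (aa).
#' @return list of motif parameters.
#' @export
motif_config <- function(c_pattern = "[GSAI]D[DN]",
                         a_pattern = "D.{4,5}D",
                         b_pattern = "G.{1,3}[ST]",
                         ac_min = 50L, ac_max = 300L) {
  list(c_pattern = c_pattern, a_pattern = a_pattern, b_pattern = b_pattern,
       ac_min = ac_min, ac_max = ac_max)
}

#' Detect catalytic A/B/C RdRp motifs
#'
#' Finds the canonical palm-domain motifs used to curate divergent RdRp
#' candidates.  Motif C is the first triad matching the configured pattern
#' (`GDD`, `SDD`, `IDD`, ... by default; non-canonical triads such as
#' `GDT` do not match and leave `motif_C_triad` absent).  Motif A is
#' searched upstream of C, preferring a match whose separation from C
#' falls inside the configured spacing window.  Motif B is searched
#' strictly between A and C; more than one match is reported as
#' `"uncertain"` rather than a firm yes.  `spacing_ok` requires motif A
#' upstream of motif C with an A-to-C separation inside the window.
#'
#' @param protein amino-acid string (>= 100 residues).
#' @param config motif patterns and spacing, see [motif_config()].
#' @return list with `has_A` (logical), `has_B` (`"yes"`, `"uncertain"`,
#'   `"no"`), `motif_C_triad` (string or NA), `positions` (named list of
#'   0-based offsets), `spacing_ok` (logical).
#' @export
find_motifs_abc <- function(protein, config = motif_config()) {
  stopifnot(nchar(protein) >= 100)
  no <- list(has_A = FALSE, has_B = "no", motif_C_triad = NA_character_,
             positions = list(A = NA_integer_, B = NA_integer_,
                              C = NA_integer_), spacing_ok = FALSE)
  mC <- regexpr(config$c_pattern, protein)
  if (mC[1] == -1) return(no)
  c_pos <- as.integer(mC[1]) - 1L  # 0-based
  triad <- substr(protein, mC[1], mC[1] + 2L)
  prefix <- substr(protein, 1, c_pos)  # residues strictly before C
  mA <- gregexpr(config$a_pattern, prefix)[[1]]
  a_pos <- NA_integer_
  if (mA[1] != -1) {
    a_starts <- as.integer(mA) - 1L
    sep <- c_pos - a_starts
    in_win <- sep >= config$ac_min & sep <= config$ac_max
    a_pos <- if (any(in_win)) a_starts[which(in_win)[1]] else a_starts[1]
  }
  has_A <- !is.na(a_pos)
  b_pos <- NA_integer_
  has_B <- "no"
  if (has_A) {
    between <- substr(protein, a_pos + 1L + attr_len(mA, a_pos), c_pos)
    off <- a_pos + attr_len(mA, a_pos)
    mB <- gregexpr(config$b_pattern, between)[[1]]
    if (mB[1] != -1) {
      b_pos <- off + as.integer(mB[1]) - 1L
      has_B <- if (length(mB) > 1) "uncertain" else "yes"
    }
  }
  spacing_ok <- has_A && (c_pos - a_pos) >= config$ac_min &&
    (c_pos - a_pos) <= config$ac_max
  list(has_A = has_A, has_B = has_B, motif_C_triad = triad,
       positions = list(A = a_pos, B = b_pos, C = c_pos),
       spacing_ok = spacing_ok)
}

# length of the A-motif match chosen at a_pos (0-based)
attr_len <- function(mA, a_pos) {
  lens <- attr(mA, "match.length")
  i <- which(as.integer(mA) - 1L == a_pos)[1]
  if (is.na(i)) 0L else as.integer(lens[i])
}

#' Curation thresholds for divergent-candidate triage
#'
#' @param retain_evalue profile E-value at or below which a candidate is
#'   retained outright (default `1e-5`).
#' @param weak_evalue profile E-value above which a candidate with no
#'   structural support is discarded as weak (default `1e-3`).
#' @param confidence structure-confidence percentage regarded as decisive
#'   (default 90).
#' @return list of thresholds.
#' @export
curation_thresholds <- function(retain_evalue = 1e-5, weak_evalue = 1e-3,
                                confidence = 90) {
  list(retain_evalue = retain_evalue, weak_evalue = weak_evalue,
       confidence = confidence)
}

#' Curate a divergent RdRp candidate
#'
#' Pure decision function combining the profile E-value, an optional
#' externally supplied structure-prediction confidence (never computed by
#' this package), and the catalytic motif annotation.  The decision grid:
#'
#' 1. a confident (> 90 per cent) *non-viral* structure assignment
#'    discards the candidate (`discarded_nonviral`);
#' 2. a profile E-value at or below `retain_evalue`, or a confident viral
#'    structure assignment, retains it (`retained`);
#' 3. a profile E-value above `weak_evalue` with no confident structural
#'    support discards it (`discarded_weak`);
#' 4. anything else lands in the grey zone and is escalated to the motif
#'    check: a present motif-C triad with acceptable A--C spacing retains
#'    the candidate, otherwise the verdict stays `uncertain`.
#'
#' @param profile_evalue positive empirical profile E-value.
#' @param structure_confidence structure-prediction confidence in percent,
#'   or NA when no structural analysis is available.
#' @param structure_hit_is_viral logical (or NA): whether the structural
#'   best hit is viral.
#' @param motif motif annotation from [find_motifs_abc()], or NULL.
#' @param thresholds see [curation_thresholds()].
#' @return list with `verdict` (one of `retained`, `discarded_nonviral`,
#'   `discarded_weak`, `uncertain`) and `reason` (the rule that fired).
#' @export
curate_candidate <- function(profile_evalue, structure_confidence = NA,
                             structure_hit_is_viral = NA, motif = NULL,
                             thresholds = curation_thresholds()) {
  stopifnot(is.finite(profile_evalue), profile_evalue > 0)
  conf <- structure_confidence
  viral <- structure_hit_is_viral
  conf_high <- !is.na(conf) && conf > thresholds$confidence
  if (conf_high && !is.na(viral) && !viral) {
    return(list(verdict = "discarded_nonviral",
                reason = "confident non-viral structure assignment"))
  }
  if (profile_evalue <= thresholds$retain_evalue) {
    return(list(verdict = "retained", reason = "profile e-value"))
  }
  if (conf_high && !is.na(viral) && viral) {
    return(list(verdict = "retained", reason = "confident viral structure"))
  }
  if (profile_evalue > thresholds$weak_evalue) {
    return(list(verdict = "discarded_weak",
                reason = "weak profile and no structural support"))
  }
  # grey zone: escalate to catalytic motifs
  if (!is.null(motif) && !is.na(motif$motif_C_triad) && motif$spacing_ok) {
    return(list(verdict = "retained",
                reason = "grey-zone e-value rescued by catalytic motifs"))
  }
  list(verdict = "uncertain", reason = "grey-zone e-value, motifs inconclusive")
}
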