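aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a protein to a target divergence
#'
#' Substitutes exactly `round(divergence * L)` positions (chosen outside
#' `mask`) with replacement residues sampled with probability proportional
#' to `2^(s/2)` where `s` is the BLOSUM62 score against the original
#' residue -- a scoring-matrix-weighted sampler that prefers conservative
#' substitutions, as real divergence does.  No indels are introduced, so
#' percent identity against the source stays well defined.
#'
#' @param protein amino-acid string.
#' @param divergence target substitution fraction in `[0, 0.7]`.
#' @param mask 1-based positions never mutated (e.g. catalytic motifs).
#' @return mutated protein string.
#' @export
mutate_protein <- function(protein, divergence, mask = integer(0)) {
  stopifnot(divergence >= 0, divergence <= 0.7)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  L <- length(chars)
  free <- setdiff(seq_len(L), mask)
  n_sub <- round(divergence * L)
  if (n_sub == 0) return(protein)
  if (n_sub > length(free)) stop("divergence target exceeds mutable positions")
  pos <- sample(free, n_sub)
  aa20 <- aa_alphabet()
  b62 <- blosum62_matrix()[aa20, aa20]
  for (p in pos) {
    orig <- chars[p]
    w <- 2^(b62[orig, ] / 2)
    w[orig] <- 0
    chars[p] <- sample(aa20, 1, prob = w)
  }
  paste(chars, collapse = "")
}

protein_divergence <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca != cb)
}

# Remove accidental motif-C-pattern triads so the first (or only) match is
# the planted one; the middle D of an unwanted match becomes E.
scrub_triads <- function(protein, keep_at = NA_integer_,
                         region_end = nchar(protein),
                         config = motif_config()) {
  repeat {
    m <- gregexpr(config$c_pattern, protein)[[1]]
    if (m[1] == -1) break
    starts0 <- as.integer(m) - 1L
    bad <- starts0[(is.na(keep_at) | starts0 != keep_at) &
                     starts0 < region_end]
    if (length(bad) == 0) break
    p <- bad[1] + 2L  # 1-based position of the middle D
    substr(protein, p, p) <- "E"
  }
  protein
}

# Sample codons for a protein; `exclude` removes codons from the pool
# (e.g. those whose reverse complement is a stop), `force` is a named
# integer->codon map overriding specific 1-based positions.
reverse_translate <- function(protein, code = genetic_code("standard"),
                              exclude = character(0), force = NULL) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  pool <- split(names(code$table), unname(code$table))
  pool <- lapply(pool, function(x) setdiff(x, exclude))
  codons <- vapply(chars, function(a) {
    cands <- pool[[a]]
    if (length(cands) == 0) stop("no codon available for residue ", a)
    if (length(cands) == 1) cands else sample(cands, 1)
  }, character(1), USE.NAMES = FALSE)
  if (!is.null(force)) {
    codons[as.integer(names(force))] <- unname(force)
  }
  paste(codons, collapse = "")
}

# Motif layout planted in every synthetic RdRp (0-based offsets).
rdrp_motif_layout <- function() {
  list(A = 180L, A_seq = "DYSKFD", B = 240L, B_seq = "GAMS", C = 300L)
}

#' Build a synthetic labelled reference database
#'
#' Emulates a taxonomy-annotated protein collection at desk scale: RdRp
#' proteins from several RNA virus families, each family a cloud of
#' members around a common ancestor, all carrying the catalytic A/B/C
#' motifs at realistic spacing (motif C triads vary by family, including
#' the non-canonical `SDD` and `IDD`); plus cellular proteins from
#' eukaryotic algal lineages, bacteria and archaea, one rbcL per
#' eukaryotic phylum, and reverse-transcriptase-like decoys (remotely
#' RdRp-related cellular sequences with disrupted catalytic triads) that
#' exercise the reciprocal-confirmation filter.  Deterministic given the
#' seed; different seeds give disjoint sequence sets with an identical
#' schema.
#'
#' @param seed integer seed.
#' @param n_viral number of viral RdRps (>= 10; distributed over 7
#'   families).
#' @param n_cellular number of cellular proteins (>= 10).
#' @param out_dir optional directory; when given, `proteins.fasta` and
#'   `taxonomy.tsv` are written there.
#' @return reference database data.frame (see [read_reference_db()]).
#' @export
make_reference_db <- function(seed, n_viral = 42L, n_cellular = 63L,
                              out_dir = NULL) {
  stopifnot(n_viral >= 10, n_cellular >= 10)
  fams <- data.frame(
    family = c("Narnaviridae", "Mitoviridae", "Leviviridae", "Totiviridae",
               "Partitiviridae", "Marnaviridae", "Qinviridae"),
    kingdom = "Viruses",
    phylum = c("Lenarviricota", "Lenarviricota", "Lenarviricota",
               "Duplornaviricota", "Duplornaviricota", "Pisuviricota",
               "Negarnaviricota"),
    motif_c = c("GDD", "GDD", "GDD", "SDD", "GDD", "GDD", "IDD"),
    stringsAsFactors = FALSE)
  layout <- rdrp_motif_layout()
  mask <- c(layout$A + seq_len(nchar(layout$A_seq)),
            layout$B + seq_len(nchar(layout$B_seq)),
            layout$C + 1:3)
  per_fam <- diff(round(seq(0, n_viral, length.out = nrow(fams) + 1)))
  db <- with_seed(seed, {
    rows <- list()
    ancestors <- list()
    for (fi in seq_len(nrow(fams))) {
      anc <- random_protein(450L)
      substr(anc, layout$A + 1L, layout$A + nchar(layout$A_seq)) <- layout$A_seq
      substr(anc, layout$B + 1L, layout$B + nchar(layout$B_seq)) <- layout$B_seq
      substr(anc, layout$C + 1L, layout$C + 3L) <- fams$motif_c[fi]
      anc <- scrub_triads(anc, keep_at = layout$C, region_end = layout$C)
      ancestors[[fams$family[fi]]] <- anc
      for (mi in seq_len(per_fam[fi])) {
        mem <- mutate_protein(anc, runif(1, 0.08, 0.25), mask = mask)
        mem <- scrub_triads(mem, keep_at = layout$C, region_end = layout$C)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("RdRp_%s_%02d", fams$family[fi], mi), seq = mem,
          kingdom = "Viruses", phylum = fams$phylum[fi],
          family = fams$family[fi],
          species = sprintf("%s virus %d", sub("viridae", "virus",
                                               fams$family[fi]), mi),
          is_viral = TRUE, is_rdrp = TRUE, stringsAsFactors = FALSE)
      }
    }
    euk_phyla <- c("Bacillariophyta", "Haptophyta", "Chlorophyta",
                   "Rhodophyta", "Dinophyceae")
    n_decoy <- 4L
    n_rbcl <- length(euk_phyla)
    n_plain <- n_cellular - n_decoy - n_rbcl
    groups <- data.frame(
      kingdom = c(rep("Eukaryota", length(euk_phyla)), "Bacteria",
                  "Bacteria", "Archaea"),
      phylum = c(euk_phyla, "Proteobacteria", "Actinobacteria",
                 "Euryarchaeota"), stringsAsFactors = FALSE)
    per_grp <- diff(round(seq(0, n_plain, length.out = nrow(groups) + 1)))
    for (gi in seq_len(nrow(groups))) {
      for (mi in seq_len(per_grp[gi])) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("CELL_%s_%02d", groups$phylum[gi], mi),
          seq = random_protein(sample(250:400, 1)),
          kingdom = groups$kingdom[gi], phylum = groups$phylum[gi],
          family = "cellular",
          species = sprintf("%s sp. %d", groups$phylum[gi], mi),
          is_viral = FALSE, is_rdrp = FALSE, stringsAsFactors = FALSE)
      }
    }
    for (ph in euk_phyla) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("rbcL_%s", ph), seq = random_protein(476L),
        kingdom = "Eukaryota", phylum = ph, family = "RuBisCO",
        species = sprintf("%s sp. rbcL", ph),
        is_viral = FALSE, is_rdrp = FALSE, stringsAsFactors = FALSE)
    }
    for (di in seq_len(n_decoy)) {
      src <- ancestors[[((di - 1L) %% length(ancestors)) + 1L]]
      dec <- mutate_protein(src, 0.55, mask = integer(0))
      dec <- scrub_triads(dec)  # no catalytic triad anywhere
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("CELL_RT_decoy_%02d", di), seq = dec,
        kingdom = "Eukaryota",
        phylum = euk_phyla[((di - 1L) %% length(euk_phyla)) + 1L],
        family = "retroelement",
        species = sprintf("retroelement %d", di),
        is_viral = FALSE, is_rdrp = FALSE, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  rownames(db) <- NULL
  validate_reference_db(db)
  if (!is.null(out_dir)) write_reference_db(db, out_dir)
  attr(db, "seed") <- seed
  db
}

#' Family profiles from the reference database
#'
#' Builds one PSSM per viral family from the family members (which are
#' equal-length, substitution-only descendants of a common ancestor and
#' hence trivially aligned), restricted to the core region spanning the
#' catalytic A/B/C motifs.
#'
#' @param db reference database from [make_reference_db()].
#' @param core 1-based column range of the core region (default covers
#'   the planted motif layout with flanks).
#' @param pseudocount passed to [build_profile()].
#' @return named list of `rdrp_profile` objects.
#' @export
rdrp_profiles <- function(db, core = c(150L, 330L), pseudocount = 1) {
  vir <- db[db$is_rdrp, , drop = FALSE]
  fams <- unique(vir$family)
  out <- list()
  for (f in fams) {
    seqs <- substr(vir$seq[vir$family == f], core[1], core[2])
    if (length(seqs) < 3) next
    out[[f]] <- build_profile(seqs, pseudocount = pseudocount, name = f)
  }
  out
}

#' Construct a virus template
#'
#' @param name virus name used in contig ids and the truth table.
#' @param architecture one of `narna_single_orf_ambigrammatic`,
#'   `mito_code_single_orf`, `toti_cp_rdrp`, `partiti_bisegmented`,
#'   `marna_polyprotein`.
#' @param family source family in the reference database.
#' @param target_divergence protein divergence from the source RdRp
#'   (refused above 0.7, beyond detectability by design).
#' @param code_id genetic code used by the genome.
#' @return template list.
#' @export
virus_template <- function(name, architecture, family,
                           target_divergence,
                           code_id = if (architecture ==
                                         "mito_code_single_orf") "mito"
                                     else "standard") {
  architecture <- match.arg(architecture,
    c("narna_single_orf_ambigrammatic", "mito_code_single_orf",
      "toti_cp_rdrp", "partiti_bisegmented", "marna_polyprotein"))
  stopifnot(target_divergence <= 0.7)
  list(name = name, architecture = architecture, family = family,
       target_divergence = target_divergence, code_id = code_id)
}

# codons whose reverse complement is a stop (excluded from ambigrammatic
# coding so the reverse strand stays stop-free in the aligned frame)
rc_stop_codons <- function() c("TTA", "CTA", "TCA")

utr_nt <- function(n) random_nt(n)

#' Generate a synthetic viral genome from a template
#'
#' The RdRp ORF is a mutated copy of a reference-database RdRp at the
#' template's target divergence (substitution only, catalytic motifs
#' preserved).  Architecture determines the layout: the narna-like
#' template keeps the reverse strand stop-free over the RdRp ORF
#' (ambigrammatic); the mito-like template encodes tryptophans as `TGA`
#' so the full-length ORF exists only under the mitochondrial code; the
#' toti-like template carries a coat protein ORF 5' of the RdRp ORF on
#' one segment; the partiti-like template emits two segments (RdRp and
#' CP); the marna-like template encodes the RdRp as the C-terminal domain
#' of a single long polyprotein ORF.  ORFs are stop-bounded with >= 57 nt
#' flanks so completeness calls are well defined.
#'
#' @param template from [virus_template()].
#' @param seed integer seed.
#' @param ref_db reference database ([make_reference_db()]).
#' @return list with `name`, `segments` (named nt vector),
#'   `rdrp_segment`, `rdrp_orf` (0-based half-open nt span of the RdRp
#'   ORF on its segment), `protein`, `source_id`, `realized_divergence`,
#'   `code_id`, `architecture`, `family`.
#' @export
make_viral_genome <- function(template, seed, ref_db) {
  stopifnot(template$target_divergence <= 0.7)
  layout <- rdrp_motif_layout()
  mask <- c(layout$A + seq_len(nchar(layout$A_seq)),
            layout$B + seq_len(nchar(layout$B_seq)),
            layout$C + 1:3)
  members <- ref_db[ref_db$is_rdrp & ref_db$family == template$family, ,
                    drop = FALSE]
  if (nrow(members) == 0) stop("no reference RdRps for family ",
                               template$family)
  members <- members[order(members$id), , drop = FALSE]
  src <- members[1, ]
  with_seed(seed, {
    prot <- mutate_protein(src$seq, template$target_divergence, mask = mask)
    arch <- template$architecture
    wpos <- integer(0)
    if (arch == "mito_code_single_orf") {
      wpos <- round(nchar(prot) * c(0.22, 0.45, 0.70))
      for (p in wpos) substr(prot, p, p) <- "W"
    }
    prot <- scrub_triads(prot, keep_at = layout$C, region_end = layout$C)
    realized <- protein_divergence(prot, src$seq)
    code <- genetic_code(template$code_id)
    segments <- character(0)
    if (arch == "narna_single_orf_ambigrammatic") {
      orf_nt <- reverse_translate(prot, code, exclude = rc_stop_codons())
      segs <- assemble_segment(orf_nt)
      segments <- setNames(segs$seq, template$name)
      rdrp_seg <- template$name; rdrp_orf <- segs$orf
    } else if (arch == "mito_code_single_orf") {
      force <- setNames(rep("TGA", length(wpos)), wpos)
      orf_nt <- reverse_translate(prot, code, exclude = "TGA", force = force)
      segs <- assemble_segment(orf_nt)
      segments <- setNames(segs$seq, template$name)
      rdrp_seg <- template$name; rdrp_orf <- segs$orf
    } else if (arch == "toti_cp_rdrp") {
      cp <- random_protein(300L)
      cp_nt <- reverse_translate(cp, code)
      orf_nt <- reverse_translate(prot, code)
      utr5 <- paste0(utr_nt(57), "TAA")
      spacer <- paste0("TAA", utr_nt(30), "TAA")
      utr3 <- paste0("TAA", utr_nt(57))
      seq <- paste0(utr5, cp_nt, spacer, orf_nt, utr3)
      start <- nchar(utr5) + nchar(cp_nt) + nchar(spacer)
      segments <- setNames(seq, template$name)
      rdrp_seg <- template$name
      rdrp_orf <- c(start, start + nchar(orf_nt))
    } else if (arch == "partiti_bisegmented") {
      orf_nt <- reverse_translate(prot, code)
      segs <- assemble_segment(orf_nt)
      cp_nt <- reverse_translate(random_protein(250L), code)
      cp_segs <- assemble_segment(cp_nt)
      segments <- setNames(c(segs$seq, cp_segs$seq),
                           paste0(template$name, c("_seg1", "_seg2")))
      rdrp_seg <- paste0(template$name, "_seg1"); rdrp_orf <- segs$orf
    } else { # marna_polyprotein
      nterm <- scrub_triads(random_protein(350L))
      poly <- paste0(nterm, prot)
      orf_nt <- reverse_translate(poly, code)
      segs <- assemble_segment(orf_nt)
      segments <- setNames(segs$seq, template$name)
      rdrp_seg <- template$name; rdrp_orf <- segs$orf
    }
    list(name = template$name, segments = segments, rdrp_segment = rdrp_seg,
         rdrp_orf = rdrp_orf, protein = prot, source_id = src$id,
         realized_divergence = realized, code_id = template$code_id,
         architecture = arch, family = template$family)
  })
}

# ORF flanked by in-frame stops and 57-nt UTRs; returns the sequence and
# the 0-based half-open ORF span.
assemble_segment <- function(orf_nt, utr = 57L) {
  utr5 <- paste0(utr_nt(utr), "TAA")
  utr3 <- paste0("TAA", utr_nt(utr))
  seq <- paste0(utr5, orf_nt, utr3)
  list(seq = seq, orf = c(nchar(utr5), nchar(utr5) + nchar(orf_nt)))
}
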