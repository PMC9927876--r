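Package: rdrpscout
Title: Discovery of Divergent RNA Virus Polymerases in Culture Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects divergent RNA-dependent RNA polymerase (RdRp) sequences
    in transcriptome assemblies from mono-strain microbial eukaryote cultures.
    Provides stop-to-stop six-frame open reading frame prediction under
    standard, mitochondrial and plastid genetic codes, a local protein
    alignment search engine with best-hit and reciprocal-confirmation triage,
    position-specific scoring matrix scans with catalytic A/B/C motif
    curation for highly divergent candidates, read-based abundance estimation
    with index-hopping and reagent-contaminant filters, kingdom-level host
    profiling, endogenous viral element screening, and a synthetic
    transcriptome project generator with a machine-readable truth table for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
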