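# rdrpscout

Discovery of divergent RNA virus polymerases in mono-strain culture
transcriptomes.

## What this is for

Transcriptomes sequenced from single-strain microbial eukaryote cultures
(microalgae, other protists) are one of the few data types in which a
newly discovered RNA virus can be tied to a specific host. The catch is
that protist RNA viruses are extraordinarily divergent: the one gene
conserved across all RNA viruses — the RNA-dependent RNA polymerase
(RdRp) — is often the only detectable signal, frequently at under 50 %
amino-acid identity to anything described, and sometimes visible only
through its catalytic palm-domain motifs (A: `D-x(4,5)-D`, B:
`G-x(1,3)-[ST]`, C: the `GDD` triad and its `SDD`/`IDD` variants).

`rdrpscout` implements the full discovery and triage workflow for this
setting, end to end:

- stop-to-stop six-frame ORF prediction (>= 200 aa) under the standard,
  mitochondrial (NCBI table 4) and plastid (table 11) genetic codes —
  some mito-like virus ORFs simply do not exist under the standard table;
- an affine-gap Smith–Waterman search engine (BLOSUM62, gaps 11/1,
  E-values from fixed Karlin–Altschul constants
  `E = K·m·n·exp(−λS)`, λ = 0.267, K = 0.041) with best-hit retention,
  a translated six-frame route for short or code-broken RdRp fragments,
  and reciprocal confirmation against a mixed viral/cellular database;
- per-family PSSM scans with an empirical shuffle null (Gumbel tail) and
  a motif-based curation grid for candidates in the grey zone between
  E = 1e-5 and 1e-3, with structure-prediction confidence as a pluggable
  input;
- read-mapping abundance in reads per million, the strict cross-library
  index-hopping rule (flag anything below 0.1 % of the maximum abundance
  of the same sequence elsewhere), a 100 %-identity reagent-contaminant
  rule, greedy read-based contig extension, and comparison against the
  host rbcL expression yardstick;
- kingdom-level host profiling by closest homologs (TPM over assigned
  contigs), host proposal, and endogenous-viral-element screening against
  the host genome;
- a synthetic project generator that plants viruses of five genome
  architectures (ambigrammatic narna-like, mitochondrial-code mito-like,
  CP–RdRp toti-like, bisegmented partiti-like, polyprotein marna-like) at
  controlled divergence and abundance, together with index-hopped copies,
  a shared reagent contaminant, an integrated EVE, and a machine-readable
  truth table.

## Worked example

Simulate a compact three-library project and run discovery on it:

```r
library(rdrpscout)
dir <- tempfile("demo")
make_project(dir, seed = 7, config = compact_project_config())
res <- run_discovery(dir, default_config(seed = 7))
res$candidates
```

```
  library_id    contig_id   detection_route       family pct_identity   rpm
1        L01 L01_V01narna   orf_blastp_like Narnaviridae         75.1 1e+05
2        L02  L02_V02mito translated_search  Mitoviridae         69.6 5e+03
  genome_status  code_id motif_c ambigrammatic           rbcl_class
1   full_length standard     GDD          TRUE comparable_or_higher
2   full_length     mito     GDD         FALSE comparable_or_higher
    proposed_host
1 Bacillariophyta
2      Haptophyta
```

Both planted viruses are reported. The narna-like virus was found by the
ORF route at 75 % identity to its nearest reference, is full length,
ambigrammatic (its reverse strand is stop-free across the ORF), and as
abundant as the host's rbcL transcript — consistent with active
replication. The mito-like virus was invisible to the ORF route (its ORF
is interrupted by `TGA` under the standard code) and was recovered by the
translated search, then re-annotated as a clean full-length ORF under the
mitochondrial code (`code_id = mito`).

The filters and the EVE screen did their work on everything else:

```r
res$filters[res$filters$flag != "pass", ]
```

```
  library_id        contig_id                flag
1        L01      L01_reagent reagent_contaminant
3        L02      L02_reagent reagent_contaminant
6        L03 L03_hop_V01narna       index_hopping
```

```r
res$eve
```

```
  library_id    contig_id    verdict coverage_frac
1        L01 L01_V01narna  exogenous     0.0000000
2        L02  L02_V02mito  exogenous     0.5312925
3        L03      L03_eve likely_EVE     1.0000000
```

The reagent contaminant (identical in two of three libraries) and the
index-hopped copy of the L01 virus (a single read, 0.05 % of the source
abundance) are flagged and never reach the report; the RdRp-like sequence
in L03 matches its own host genome over its full length and is classified
as a likely endogenous viral element rather than an exogenous virus.

`run_discovery(..., out_dir = )` additionally writes `candidates.tsv`,
`kingdom_profiles.tsv`, `filters.tsv`, `eve.tsv`, a per-decision
`discovery_log.tsv` and `run.json`. A thin command-line wrapper is
installed at `inst/scripts/rdrpscout.R`
(`simulate` / `discover` / `report`).

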