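---
title: "Detecting divergent RNA virus polymerases in culture transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting divergent RNA virus polymerases in culture transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdrpscout)
```

## The problem

Transcriptomes of mono-strain microbial eukaryote cultures (microalgae in
particular) are a rare setting in which an RNA virus can be attributed to a
specific host: the culture contains one eukaryote strain, sometimes
accompanied by known bacterial associates, and anything replicating in it
must infect something in that small community. The difficulty is that
RNA viruses of protists are extremely divergent — often well under 50 %
amino-acid identity to their closest described relative — so discovery
hinges on one protein: the RNA-dependent RNA polymerase (RdRp), the only
hallmark gene conserved across all RNA viruses, recognisable by homology
and by its catalytic palm-domain motifs (A, B and C; motif C is canonically
Gly-Asp-Asp).

`rdrpscout` implements the complete triage workflow for this setting as a
tested, reusable pipeline: ORF prediction under several genetic codes,
similarity searches with best-hit and reciprocal-confirmation rules,
profile and motif rescue of candidates too divergent for pairwise search,
abundance-based contamination filters, kingdom-level host profiling, and
endogenous-viral-element (EVE) screening. Because real culture collections
are large external resources, the package pairs the pipeline with a
synthetic project generator that plants viruses of known architecture,
abundance and divergence into mock libraries — so every stage can be
validated against machine-readable ground truth.

## The discovery workflow

For each library the pipeline runs, in order:

1. **ORF prediction** (`predict_orfs`): stop-to-stop translation of all six
   frames, emitting every maximal stop-free codon run of at least
   `min_aa_len = 200` amino acids. Runs truncated by contig ends are kept
   (no START codon is required), because partial virus genomes routinely
   lack their 5' end. Coordinates are 0-based half-open on the forward
   strand, with the strand recorded separately.
2. **Protein search** (`search_protein`): each ORF against the full
   labelled protein database, best hit only, E-value cutoff `1e-3`. ORFs
   whose best hit is a viral RdRp become candidates; ORFs with no hit at
   all are *orphans* and are remembered for step 5.
3. **Translated search**: all six frame translations of every contig
   against the RdRp-only subset of the database, best hit per contig at
   the same cutoff. This is the sensitive route: it recovers RdRp
   fragments shorter than the 200-aa ORF floor and genomes whose ORF is
   interrupted under the standard code (internal stops are carried into
   the frame translation and locally penalised, not fatal).
4. **Reciprocal confirmation** (`reciprocal_confirm`): every candidate is
   re-searched against the full mixed viral/cellular database. A candidate
   whose best hit (by bit score; ties broken by E-value then target id) is
   cellular is discarded. This removes host genes that weakly resemble
   RdRps, including reverse-transcriptase-like sequences.
5. **Profile/motif rescue** (`scan_profile`, `find_motifs_abc`,
   `curate_candidate`): orphan ORFs are scanned against per-family RdRp
   profiles; retention follows the decision grid described below.
6. **Abundance estimation** (`map_reads`): reads are mapped back to the
   library's contigs by exact seeding; abundances are reported as reads
   per million (rpm). The host rbcL gene is quantified the same way as an
   expression yardstick.
7. **Contamination filters**: candidates are clustered across libraries
   (>= 99 % nucleotide identity over >= 90 % mutual coverage) and two rules
   are applied — the index-hopping rule and the reagent-contaminant rule
   (below).
8. **Extension and re-annotation** (`extend_contig`): surviving candidate
   contigs are greedily extended from their reads, then re-annotated under
   the standard, mitochondrial and plastid genetic codes; the
   code/ORF pair that best matches the candidate's nearest reference is
   kept.
9. **Host profiling** (`kingdom_profile`, `propose_host`): contigs are
   assigned to kingdoms via their closest homologs, abundances summed as
   TPM, and each candidate is attributed to the dominant eukaryotic
   lineage — or to Bacteria when its family is prokaryote-infecting and
   bacterial contigs are present.
10. **EVE screening** (`detect_eve`): each candidate's nucleotide sequence
    is aligned against the library's host genome when one is available; a
    strong, extensive match reclassifies the candidate as a likely
    endogenous element and removes it from the exogenous-virus report.

Every discard at every stage is written to the discovery log with the rule
that fired, so the automated decisions can be audited the way a manual
curation would be.

## Alignment engine and E-values

The search stages are backed by an affine-gap Smith–Waterman aligner
(C++ core) under BLOSUM62 with gap penalties 11/1, where a gap of total
length $k$ costs $11 + k$. Unknown residues are mapped to `X` and score 0
against everything; the stop symbol `*` keeps its usual −4 so translated
frames containing stops still anchor local alignments. Percent identity is
computed over aligned columns with gap columns in the denominator.

Raw scores are converted with fixed Karlin–Altschul-style constants
($\lambda = 0.267$, $K = 0.041$; the values commonly used with
BLOSUM62/11/1), giving $E = K m n e^{-\lambda S}$ and bit score
$(\lambda S - \ln K)/\ln 2$. This is a deliberate calibration
approximation — no per-search parameter fitting is performed — and the
package makes no claim of reproducing any external search tool's E-values.

Searches are seeded: only targets sharing exact k-mers with the query are
aligned. `search_protein` defaults to $k = 3$, at which seeding is exact
at the database sizes the package targets (every alignment that can reach
the reporting threshold shares a 3-mer; this is asserted against the
exhaustive aligner in the test suite). The pipeline's bulk scans instead
use $k = 4$ and require 2–3 distinct shared k-mers, a speed profile chosen
because genuine homologs in the detectability range (<= 50 % divergence
over ~450 aa) share dozens of 4-mers; this profile is validated end-to-end
against planted truth rather than against the exhaustive aligner.

One addition to the similarity triage proved necessary: a candidate's hit
must cover at least `min_target_coverage = 0.2` of the matched reference
RdRp. With a correctly calibrated E-value, a cutoff of `1e-3` admits a few
short random high-scoring segments per project across thousands of frame
queries; these spurious hits span only ~25 residues of a 450-residue
reference, while every genuine candidate — even a 150-aa fragment — covers
a third or more. The coverage rule is the package's automated counterpart
of quality-checking hits by alignment coverage before accepting them.

## Profile scanning and the curation grid

Divergent candidates beyond the reach of pairwise search are scored with
per-family position-specific scoring matrices built from the reference
RdRps (`build_profile`: per-column log-odds against a uniform background
with a pseudocount; columns over 50 % gaps dropped). A scan
(`scan_profile`) takes the best ungapped window score over all offsets and
converts it to an empirical E-value by shuffling the query's residues
(`n_shuffles = 200` by default), fitting a Gumbel location-scale law to
the null best-window scores by the method of moments, and scaling the
upper-tail probability by the number of profiles searched. The scan is
seeded and reproducible bit for bit.

Retention combines three signals — the profile E-value, an *externally
supplied* structure-prediction confidence (the package never computes
structural homology; the column is a pluggable per-candidate input), and
the catalytic motifs:

| profile E-value | structure | motifs | verdict |
|---|---|---|---|
| any | > 90 % confident, non-viral | — | `discarded_nonviral` |
| <= 1e-5 | — | — | `retained` |
| > 1e-5 | > 90 % confident, viral | — | `retained` |
| > 1e-3 | <= 90 % or absent | — | `discarded_weak` |
| (1e-5, 1e-3] | <= 90 % or absent | motif C present, A–C spacing 50–300 aa | `retained` |
| (1e-5, 1e-3] | <= 90 % or absent | otherwise | `uncertain` |

The grey zone between `1e-5` and `1e-3` is resolved by the motifs because
a plain e-value threshold alone cannot express how motif evidence
should arbitrate borderline candidates; this
interpretation is a documented design choice, and the grid is enforced as
a pure total function with an exhaustive test.

Motif definitions are configuration, not code (`motif_config`): motif C is
the first triad matching `[GSAI]D[DN]` (so the canonical GDD, the SDD of
toti-like viruses and the IDD of qin-like viruses all match, while GDT
does not); motif A is `D-x(4,5)-D` upstream; motif B is `G-x(1,3)-[ST]`
between A and C, reported as *uncertain* when it matches ambiguously more
than once; spacing is acceptable when the A-to-C separation lies within
50–300 residues.

## Abundance, contamination and completeness

Abundance is reads per million: mapped reads divided by the library's
total reads times $10^6$. The cross-library (index-hopping) rule compares
rpm — not raw counts — because rpm is how abundance is defined throughout;
within a cluster of libraries sharing the same sequence, any library
strictly below 0.1 % of the maximum rpm is flagged, and the maximum always
passes. The boundary is a strict less-than: a copy at exactly 0.1 %
passes. The reagent rule flags a sequence observed at exactly 100 %
identity across at least 10 % of libraries. The pipeline applies the
hopping rule first and the reagent rule to the survivors, and only to
sequences identical across at least two libraries — cross-sample identity
is undefined for a singleton, and without this ordering a hopped copy plus
its source (2 of 20 libraries) would satisfy the prevalence threshold and
be mislabelled as reagent contamination.

Contig extension is the automated version of manually walking a contig's
ends: reads overlapping a terminus exactly by at least `min_overlap = 31`
nt vote per position on the extension; a tie stops that terminus. The
interior is never modified, and the input is always a substring of the
output.

Completeness (`genome_status`) is a stated heuristic, not expert
curation: `full_length` requires the RdRp ORF to be stop-bounded on both
sides within the contig with at least 50 nt of flank on each side.

TPM (for host profiling) divides counts by feature length in kb and
normalises to $10^6$ across *assigned* contigs only, so kingdom fractions
are comparisons among classifiable sequence. The kingdom of a contig is
taken from its single best hit by bit score across the available routes;
orphan contigs (no hit at `1e-3`) are counted separately as the orphan
fraction.

## Genetic codes

Codes are NCBI translation tables: 1 (standard), 4 (mold/protozoan
mitochondrial; `TGA` = Trp) and 11 (plastid). Annotation practice in this
field usually names only the code family, not the table number, and some
taxa use other mitochondrial tables (e.g. 5), so `genetic_code()` accepts
any NCBI table id. Codons containing `N` translate to `X` and are conservatively treated
as non-stop. The re-annotation stage tries all configured codes and keeps
the one whose ORF best matches the candidate's nearest reference — this is
what turns a translated-search hit riddled with apparent stops into a
clean full-length mitochondrial-code ORF.

## The synthetic data and what it does (not) show

`make_project` emulates the abundance regime of culture transcriptome
libraries prepared without rRNA depletion: two rRNA-like contigs absorb
80 % of each library's reads, so everything else — host transcripts, an
rbcL-like gene at 0.5 %, bacterial contaminants in designated libraries,
and viruses at 0.2–2 % — is a small fraction of the data, and roughly half
of all contigs are unassignable orphans. The default project is 20
libraries at $10^5$ error-free 100-nt reads: twelve viruses spanning five
genome architectures (ambigrammatic narna-like; mitochondrial-code
mito-like; toti-like CP-5'/RdRp-3'; bisegmented partiti-like; marna-like
polyprotein) at 20–50 % protein divergence, two index-hopped copies
planted strictly below 0.1 % of their source's abundance, six entirely
virus-free libraries, a reagent contaminant identical across 15 of 20
libraries, and one EVE integrated into a host genome.

Per-element read *counts* are fixed by the configuration (rounded
fraction × depth) and only read *positions* are sampled. This makes
abundance ground truth exact, filter outcomes deterministic, and projects
byte-identical under a fixed seed.

Two generator conventions matter for interpreting results. Divergence is
introduced by substitutions only (BLOSUM62-weighted, catalytic motifs
masked), so percent identity against truth is well defined — but real
viral divergence includes indels, which the tests therefore do not
exercise. And reads are error-free on the forward strand, so read mapping
reduces to exact matching — mapping fidelity under sequencing error is
explicitly *not* the scientific content under test. Passing tests
demonstrate that the triage logic (thresholds, filters, code handling,
motif rules, EVE discrimination) behaves as specified; they do not
demonstrate robustness to assembly error, sequencing noise, codon-usage
bias or strain mixtures, none of which the generator models.

Validation problem sizes, chosen as the package's own operating points:
the full 20-library default project for recovery and specificity; fifty
independent 3-library compact projects (`compact_project_config`, 12,000
reads each) for the contamination filters; 1,000 host-derived proteins at
200 shuffles each for the profile false-positive control (observed
retention well under the 1 % bound); 100 random 3-kb contigs per genetic
code against a brute-force ORF enumerator; and 200 random pairs against
an independent alignment oracle.

## Numerical and degenerate-input conventions

Ties are broken deterministically everywhere: hits order by (bit score
desc, E-value asc, target id lexicographic); equally good read placements
go to the lexicographically first reference; consensus ties stop contig
extension. An empty contig yields an empty ORF list; a protein shorter
than a profile yields a no-scan result; a missing host genome yields the
verdict `no_genome` and a skipped EVE stage; an empty project yields an
empty report and success. Gumbel tail probabilities are floored at
1e-300 to avoid exact zeros; TPM of an all-orphan library is reported as
an empty kingdom vector rather than NaN.

## Known limitations

The E-value calibration is fixed rather than fitted, so absolute E-values
are approximations (comparisons and thresholds, which is all the workflow
uses, are well behaved). The profile stage is an ungapped PSSM scan with
an empirical null, not a full profile HMM with insert/delete states.
Nearest-reference classification stands in for phylogenetic placement:
family assignments are as good as the reference database is
representative, and no tree is inferred. Structure-based confirmation is
an input column, never computed. The completeness call is a heuristic and
configurable, not a claim of equivalence with expert genome curation.
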