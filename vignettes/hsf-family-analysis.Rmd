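---
title: "Genome-wide Hsf gene-family analysis with hsfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide Hsf gene-family analysis with hsfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsfkit)
library(dplyr)
```

## The biological problem

Heat shock transcription factors (Hsfs) are the master switches of the plant
heat-stress response: on stress they trimerize, bind heat-shock elements and
activate chaperone (Hsp) transcription. Plant genomes carry dozens of Hsf
paralogs, conventionally divided into classes A, B and C by a single
structural signature: the number of residues inserted between the two
hydrophobic heptad-repeat blocks (HR-A and HR-B) of the oligomerization
domain — 21 residues in class A, none in class B, 7 in class C. A
genome-wide family survey proceeds through a fixed sequence of stages:

1. **Mining** — translated homology search of an EST pool against reference
   Hsf proteins, contig assembly, and validation of full-length candidates.
2. **Domain annotation** — DNA-binding domain (DBD), HR-A/B blocks, nuclear
   localization/export signals (NLS/NES), AHA activator motifs, plus
   physical properties (length, pI, MW).
3. **Classification** — class from the HR-A/B insertion, subclass by
   similarity to labeled exemplars, and gene naming by chromosomal order.
4. **Genome context** — segmental/tandem duplication calling under an 80%
   coverage / 80% similarity rule, and exon–intron structures by spliced
   alignment of each CDS to its genomic locus.
5. **Molecular evolution** — Poisson-corrected distances with pairwise
   deletion, neighbor-joining trees with bootstrap, and Nei–Gojobori
   synonymous/non-synonymous substitution counting.
6. **Expression** — comparative $\Delta\Delta C_T$ quantification of qRT-PCR
   data: heat-shock response patterns and genotype comparisons.

`hsfkit` implements all six stages as composable functions over tibbles, and
adds a seeded synthetic-data generator that plants machine-readable truth
for every stage, so each detector can be validated against data whose
correct answer is known exactly.

## The synthetic-data generator: what it emulates

Every generator takes a `seed` and is byte-reproducible.

**Proteins.** `generate_hsf_protein()` builds sequences with the canonical
Hsf layout: N-terminal region, DBD sampled from the packaged consensus
profile, a class-specific linker, HR-A, the class insertion (21/0/7
residues), HR-B, a basic NLS cluster and — for class A — an AHA window and a
C-terminal NES. Linker lengths are drawn from the published class ranges
(A: 12–37, B: 16–77, C: 10–29, counted as `HR-A/B start − DBD end`).
Background segments use only polar residues, so the planted motifs are the
unique instances of their signatures. That choice makes planted-truth
recovery exact and interpretable; it also means the generator does **not**
emulate the compositional ambiguity of real proteins (weak secondary heptad
signals, chance K/R pairs), so perfect recovery on synthetic data bounds,
but does not guarantee, performance on real sequences.

**The DBD profile.** The packaged position-weight profile
(`hsf_dbd_profile()`) is built deterministically from the canonical DBD
secondary-structure layout (a four-stranded antiparallel β-sheet packed
against three α-helices, 94 columns): strand columns favor β-branched and
aromatic residues, helix columns favor helix formers, loops favor G/P/S/N.
No biological sequence is copied, so the profile carries no accession or
license dependence. Each column puts 0.6 on the consensus residue, 0.3 on
the region alphabet and 0.1 on the uniform background.

**Genomes.** `generate_family_genome()` embeds random coding genes in
random genomic background (GC 0.35 by default, plant-like) with one or two
GT..AG introns per gene. Duplicate copies are mutated to a requested
identity over a requested coverage, with substitutions placed uniformly —
the simplest model satisfying the 80/80 detector's assumptions. Tandem
cluster members are placed a few hundred bases apart; all other neighbors
are tens of kilobases apart, so distance-based tandem calling has a clean
planted answer.

**ESTs.** `generate_ests()` emits reads at evenly spaced positions tiling
the CDS (both strands, iid substitution errors). Even spacing guarantees
that at coverage ≥ 2 consecutive reads overlap, making the
assembly-identity property deterministic; real EST coverage is of course
not uniform, which is one reason assembly of real data can fragment where
the synthetic benchmark cannot.

**Ct tables.** `generate_ct_table()` plants one of four heat-shock response
patterns per gene (unchanged, inhibited, immediate up, late up) by shifting
the target Ct by $-\log_2(\text{fold})$ per timepoint against a constant
reference gene. Defaults: 4 technical replicates ("at least four" in the
standard protocol) and Gaussian Ct noise with SD 0.15 cycles, a typical
technical-replicate scatter for SYBR qPCR. The default 40-gene pattern mix
(`default_heat_patterns()`) is 5 unchanged, 11 inhibited, 8 immediate
(strongest at 400-fold), 16 late.

## Stage-by-stage notes on the methods

### Mining

The tBlastN-style search (`search_homologs()`) translates each pool
sequence in six frames and aligns every frame to every reference with
Smith–Waterman (BLOSUM62, affine gaps 11/1, via Biostrings). Similarity is
the fraction of positive-scoring aligned columns — the "Positives"
convention — and significance is the Karlin–Altschul expectation
$E = K m n e^{-\lambda S}$ with the gapped BLOSUM62 parameters
($\lambda = 0.267$, $K = 0.041$). The acceptance threshold is stated as a
P-value ($P \approx 1 - e^{-E}$, so P and E coincide at the $10^{-4}$
scale used for validation). Defaults: similarity ≥ 0.60, E ≤ $10^{-4}$,
alignment ≥ 30 residues.

Assembly (`assemble_contigs()`) is greedy longest-overlap-first with
deterministic lexicographic tie-breaks, both read orientations, and
containment absorption. Overlap candidates are anchored on exact 16-mers at
the joining ends, then verified against the mismatch budget
(identity ≥ 0.95 by default). A greedy assembler is the right tool at this
scale — tens of reads per gene — where determinism matters more than the
scalability of a de Bruijn graph; it will not resolve repeats and is not
intended to.

Full-length validation (`validate_full_length()`) accepts a contig iff its
longest ORF matches a reference below the P threshold **and** carries both
a detectable DBD and an HR-A/B region — the same double requirement used to
discard structure-less contigs in the original survey (43 candidates → 40
genes, a ratio the acceptance script re-creates synthetically).

### Domain annotation

`detect_dbd()` scans all windows of the 94-column profile plus N-terminally
truncated hits (≥ 83 columns, admitting the short DBD variants) and
calibrates its score threshold per call as the 99.9th percentile of
best-window scores over 200 shuffles of the same protein. Calibrating on
shuffles keeps the threshold composition-aware without a fixed cutoff the
original analysis never stated; the shuffle count and percentile are
package choices.

`detect_hrab()` finds maximal runs of hydrophobic cores (L/I/V/M/F) spaced
exactly seven apart (≥ 3 cores per block) C-terminal of the DBD. The
insertion is the residue count strictly between the last HR-A core and the
first HR-B core, snapped to the nearest class signature {0, 7, 21} when
within ±2 — snapping makes classification robust to boundary wobble while
the raw value is retained as evidence.

The linker column follows the printed-table convention
`HR-A/B start − DBD end` (the arithmetic that reproduces most printed rows
exactly); rows where the printed linker disagrees with its own coordinates
are surfaced by `check_table_consistency()` rather than corrected —
as are the DBD lengths whose narrative and coordinates disagree, and the
three genes whose exon arithmetic cannot reproduce the printed protein
length (one of them because the exon total is not divisible by three).

`find_nes()` matches a generalized leucine-rich export pattern
$\Phi x_{1-3} \Phi x_{1-3} \Phi x_{0-1} \Phi$ in the C-terminal 30% of the
protein. The final spacer admits zero residues because the canonical Hsf
export motifs (the LTEQMGLL family and (L/I)(G/R)LNLM) end in two adjacent
hydrophobics; those canonical motifs are additionally matched explicitly
and flagged. `find_aha()` scores 12-residue windows by the fraction of
aromatic (W/F/Y), large hydrophobic (L/I/V) and acidic (E/D) residues
(hit at ≥ 0.6 with at least one aromatic and one acidic; overlapping hits
merged). Localization prediction is rule-based: NLS without NES → nucleus;
NLS with NES → nucleocytoplasmic shuttling; proteins with no detected NLS
(a case absent from the published family) are reported as shuttling with a
low-confidence flag rather than invented.

### Classification

Class is a function of the HR-A/B insertion alone; unsnappable insertions
are left unclassified with the raw value reported, never forced. Subclass
assignment is nearest-exemplar over the concatenated DBD + HR-A/B region
(Poisson-corrected distance on a global alignment, ties by exemplar id).
Nearest-exemplar was chosen over full phylogenetic clade membership because
it is reproducible, $O(nm)$, and consistent with clade logic when the
exemplars are clade representatives; the original survey never states a
quantitative subclass rule, so this is a declared stand-in. Gene naming
sorts by natural chromosome order, then start coordinate (or locus id when
coordinates are unavailable), then gene id.

### Genome context

The duplication rule is exactly the published one — aligned region covering
> 80% of the longer gene and > 80% similarity over the aligned region —
with "similarity" operationalized as nucleotide identity over aligned
columns of a free-end-gap global alignment, since the source defines it no
more precisely. Pairs on one chromosome within five intervening genes are
tandem; everything else is segmental. `spliced_align()` parses the CDS
against the genomic sequence exactly, requiring GT..AG introns (CT..AC on
the forward strand for minus-strand genes) with bounded backtracking at
exon boundaries; when no GT–AG chain exists it retries unconstrained and
flags the model. Mismatch-tolerant spliced alignment is out of scope: the
contract is exact recovery at zero error, with a structure-not-found error
otherwise.

### Evolution

Distances are p-distances under pairwise deletion with Poisson correction
$d = -\ln(1-p)$; $p \ge 1$ is outside the correction's domain and is
capped at 0.999 with a flag count rather than silently dropped, so
saturated bootstrap replicates cannot crash tree building. Neighbor joining
is delegated to `ape::nj` behind `build_nj()`, with labels sorted
lexicographically first (deterministic tie-breaks) and negative branch
lengths clamped to zero with a flag. Bootstrap support resamples alignment
columns with replacement and counts bipartitions of the reference tree
(1000 replicates in the classical protocol; tests use 200).

Nei–Gojobori counting is authored here: per-codon synonymous-site fractions
averaged over both sequences, observed differences classified by averaging
over all shortest mutational pathways, pathways through stop codons
excluded, and changes that would create a stop counted as non-synonymous in
the site fractions. Aggregated mutation frequencies divide the summed
differences, `Sd` and `Nd` by one shared denominator — all compared sites
under pairwise deletion — the only convention under which synonymous plus
non-synonymous frequencies sum to the total, as the published values
(0.00433 + 0.00564 ≈ 0.00996) do. Whether the original analysis used
pairwise or complete deletion for that number is unstated; pairwise is the
default and the per-pair breakdown is returned so either can be recomputed.
A Jukes–Cantor-style correction is deliberately not applied: the published
quantities are raw frequencies.

### Expression

Relative expression is $2^{-\Delta C_T}$ against the reference gene
(arithmetic mean of replicate Cts, SDs propagated in quadrature);
fold-change is $2^{-\Delta\Delta C_T}$ against the untreated control, so
the control is 1-fold by definition and a common additive Ct shift cancels
exactly. Response patterns use declared thresholds (the source gives
none): immediate up at fold(1 h) ≥ 2; late up when not immediately induced
but rising monotonically to ≥ 2 by 4 h of recovery; inhibited at
fold(1 h) ≤ 0.5 without such a rise; unchanged otherwise. Both thresholds
are arguments and are reported with the output. Genotype comparison flags a
gene when its WT/mutant ratio passes 2 (or 1/2) at any stage and reports
both the most extreme and the across-stage geometric-mean ratio; no
significance testing is layered on top because the quantification itself
reports none.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at family scale:
40-gene families, 8–10-gene genomes for per-seed property checks (100
seeds for the duplication caller, with planted identities and coverages at
least 0.04 away from the 80/80 boundary so rounding cannot flip a
decision), trees up to 8 taxa against exhaustive or additive-metric
oracles, 200-replicate bootstraps, and 100-gene Ct tables. Bisection for
pI runs to $10^{-3}$ pH against a $10^{-4}$ grid oracle; MW uses average
residue masses with one water (18.0153 Da); both tables ship as TSV so the
"online calculator" of the original workflow becomes a pinned, versioned
input. All RNG flows through explicit seeds; internal calibrations
(DBD shuffle thresholds) save and restore the caller's RNG state.

## Known limitations

* The synthetic proteins' polar backgrounds make motif recovery exact;
  real proteins will produce borderline heptad and NLS calls that the
  snapping and evidence columns are designed to surface, not resolve.
* The greedy assembler targets tens of reads per transcript, not
  genome-scale read sets, and does not model indel sequencing errors.
* Spliced alignment requires exact CDS/genome agreement; diverged
  cross-species mappings need an external spliced aligner.
* Subclass labels are only as good as the exemplar set; the package does
  not re-derive the A1–A9/B1–B5 nomenclature.
* The expression module implements no amplification-efficiency correction
  and no inferential statistics, matching the quantification it mirrors.
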