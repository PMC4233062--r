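# hsfkit

Genome-wide analysis of the plant heat shock transcription factor (Hsf)
gene family, from raw EST pools to classified, mapped, dated and
expression-profiled genes.

Hsfs drive the transcriptional heat-stress response: they trimerize through
a hydrophobic heptad-repeat region (HR-A/B), bind heat-shock promoter
elements through a conserved DNA-binding domain (DBD), and activate
chaperone expression. Plant genomes carry large Hsf families whose classes
A, B and C are defined by a single structural signature — the insertion
between the HR-A and HR-B heptad blocks: **21 residues (class A), 0
(class B), 7 (class C)**. `hsfkit` implements the full family-survey
pipeline for researchers characterizing such a family in a newly sequenced
or under-annotated genome:

* **Mining** — six-frame translated homology search against reference Hsfs
  (Smith–Waterman, BLOSUM62, Karlin–Altschul E-values
  `E = K·m·n·exp(−λS)`), greedy contig assembly, and full-length validation
  requiring both a DBD and an HR-A/B region.
* **Annotation** — profile-based DBD detection, heptad-repeat scanning
  (`H-x6-H-x6-H`, H ∈ {L,I,V,M,F}), NLS/NES/AHA motif finders, pI by
  bisection on a pinned Bjellqvist pKa table, MW from average residue
  masses.
* **Classification** — class from the HR-A/B insertion (snapped to
  {21, 0, 7} within ±2, raw value retained), subclass by nearest labeled
  exemplar (Poisson-corrected distance over DBD + HR-A/B), gene naming by
  chromosomal order.
* **Genome context** — duplication calling under the 80% coverage / 80%
  similarity rule with segmental/tandem typing, tandem-cluster detection,
  and exact spliced alignment of CDS to genomic loci (GT..AG introns).
* **Evolution** — Poisson-corrected distances with pairwise deletion,
  neighbor-joining trees with column-bootstrap support, and Nei–Gojobori
  synonymous/non-synonymous substitution counting
  (`d = −ln(1 − p)`; unweighted shortest mutational pathways).
* **Expression** — comparative ΔΔCT quantification
  (`fold = 2^(−ΔΔCT)`), heat-shock response-pattern classification
  (unchanged / inhibited / immediate up / late up), and WT-vs-mutant
  genotype comparison.
* **Synthetic data** — seeded generators that plant machine-readable truth
  for every stage (domain coordinates, duplication pairs, substitution
  counts, response patterns), so every detector is testable end to end.

The published reference tables of the 40-member Upland cotton D-subgenome
family ship as plain-TSV fixtures (`gh_table1()`, `gh_table2()`,
`gh_table3()`), together with a consistency checker that reports — rather
than corrects — the rows whose printed values disagree with their own
coordinates.

## Worked example

Generate a small synthetic family, annotate the domain architecture and
classify it:

```r
library(hsfkit)
library(dplyr)

fam <- generate_hsf_family(n_a = 4, n_b = 3, n_c = 1, seed = 1)
ann <- annotate_hsf(fam$proteins, seed = 1)
cls <- classify_hsf(ann)
select(cls, id, dbd_start, dbd_end, linker_length, insertion_raw, class, localization)
#> # A tibble: 8 × 7
#>   id      dbd_start dbd_end linker_length insertion_raw class localization
#>   <chr>       <int>   <int>         <int>         <int> <chr> <chr>
#> 1 synHsf1        13     106            30            21 A     nucleus+cytoplasm
#> 2 synHsf2        22     115            23            21 A     nucleus+cytoplasm
#> 3 synHsf3        16     109            26            21 A     nucleus+cytoplasm
#> 4 synHsf4        21     114            33            21 A     nucleus+cytoplasm
#> 5 synHsf5        12     105            56             0 B     nucleus
#> 6 synHsf6        15     108            38             0 B     nucleus
#> 7 synHsf7        13     106            16             0 B     nucleus
#> 8 synHsf8        16     109            20             7 C     nucleus
```

Each row is one protein: the DBD window located by the profile scan, the
linker length (`hra_start − dbd_end`, the printed-table convention), the
raw HR-A/B insertion, and the class it implies — 21 → A, 0 → B, 7 → C.
Class A proteins carry a planted C-terminal NES, so they are predicted to
shuttle between nucleus and cytoplasm; B and C members with an NLS only are
called nuclear.

Heat-shock response classification from a replicate-resolved Ct table:

```r
tab <- generate_ct_table(default_heat_patterns()[c(1, 17, 20, 30), ], seed = 1)
classify_heat_response(tab$ct)
#> # A tibble: 4 × 5
#>   gene     fold_1h fold_2h fold_4h pattern
#>   <chr>      <dbl>   <dbl>   <dbl> <chr>
#> 1 synHsf1    1.07    0.943    1.05 unchanged
#> 2 synHsf17 462.     86.5     24.7  immediate_up
#> 3 synHsf20  30.1     5.60     1.74 immediate_up
#> 4 synHsf30   0.410   1.55     3.74 late_up
```

Fold-changes are `2^(−ΔΔCT)` relative to the untreated control (CK = 1 by
construction); `synHsf17` is the planted strongest responder (~400-fold
after 1 h of heat, decaying through recovery), and `synHsf30` shows the
late pattern — suppressed at 1 h, rising past 2-fold during recovery.

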