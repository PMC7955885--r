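---
title: "Methods: sweep scanning, LTR dating, satellite and NLR annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scanning, LTR dating, satellite and NLR annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napusweep)
```

napusweep packages the bespoke downstream computations of a chromosome-scale
allopolyploid genome project — sweep scans between cultivar ecotype groups,
LTR retrotransposon dating, centromeric satellite detection and NLR
annotation — as one tested toolkit. This vignette documents the models, the
tunable parameters and their defaults, the synthetic-data generators used for
validation, and the numerical choices made where the methods literature
leaves the details open.

## Windowed diversity and differentiation

For one group, per-site nucleotide diversity over the $n_j$ non-missing
haploid calls at site $j$ with $c_{ref}$ reference and $c_{alt}$ alternate
alleles is the probability that two sampled haplotypes differ,

$$\pi_j = \frac{c_{ref}\,c_{alt}}{\binom{n_j}{2}},$$

and window π sums $\pi_j$ over the sites of a window and divides by the
*nominal* window length: monomorphic and unobserved bases contribute zero,
matching the convention of the windowed popgen tools this reimplements.
Sites with fewer than two calls in a group are skipped.

Between two groups, each site contributes the Weir & Cockerham (1984)
variance components for diploids — $a$ (among populations), $b$ (among
individuals within populations) and $c$ (within individuals) — computed from
per-group sample sizes, allele frequencies and observed heterozygosities.
Window F~ST~ is the ratio of sums $\sum a / \sum(a+b+c)$ ("weighted"
estimator). Two numerical choices matter:

- sites where either group has fewer than two genotyped diploids are
  excluded (the $\bar n - 1$ and $n_c$ terms degenerate below that);
- negative F~ST~ values are retained, not clamped at zero — clamping would
  distort the empirical 5% tail used downstream. A window whose
  $\sum(a+b+c)$ is zero has undefined F~ST~ and is excluded from quantiles.

The window grid is anchored at position 0 of each chromosome (default 100 kb
windows sliding by 10 kb); trailing windows whose nominal end passes the
chromosome end are computed but flagged `partial`.

Unit checks pin the estimator to hand-enumerated cases: a fixed difference
between two ten-diploid populations gives F~ST~ = 1 exactly, and the
symmetric case (both populations five hom-ref plus five hom-alt) gives
$a = -0.25/9$, $b = (10/9)\cdot 0.25$, $c = 0$, hence F~ST~ = −1/9. Window π
is checked against a brute-force all-pairs Hamming oracle on up to eight
haplotypes at 10^-12^ tolerance.

## Sweep calling by joint empirical tails

A sweep leaves two joint signatures: elevated differentiation and diversity
loss in the selected group. `call_sweeps()` therefore intersects two
empirical-quantile filters: F~ST~ in the upper `q_fst` tail, and the window π
ratio (numerator group / denominator group) in the lower `q_pi` tail
(numerator selected) or upper tail (denominator selected). Defaults are
`q_fst = q_pi = 0.05`; 0.01 is accepted for stricter scans. The thresholds
are computed genome-wide, not per chromosome.

`empirical_threshold()` defines the upper tail as the smallest value $v$ with
$\#\{x \ge v\} \le \lceil qN \rceil$, keeping ties together — a tie crossing
the nominal boundary shrinks the retained set rather than splitting
arbitrarily. π ratios with a zero denominator and positive numerator are
+Inf sentinels that always sit in the upper tail; windows with zero diversity
in both groups carry no ratio and are excluded with a log message.

Significant windows of the same selected group that overlap or abut merge
into regions; with 100 kb windows at 10 kb steps, per-window reporting would
be redundant, and region counts and spans are what such scans report.
Annotated overlap (genes, NLR ids, QTL intervals) uses a one-base
intersection rule on 0-based half-open regions versus 1-based inclusive GFF3
genes.

## SNP effects

`classify_snp_effects()` emits one record per (SNP, overlapping gene):
`exon` when the site falls in an exon/CDS of that gene, `intron` otherwise
inside the gene, `upstream`/`downstream` within a strand-aware flank
(default 5 kb — the annotation-tool convention; the distance is
configurable), and one `intergenic` record for SNPs touching nothing. A SNP
inside a CDS is additionally translated (phase- and strand-aware, standard
code) into missense / synonymous / stop_gained / stop_lost. A CDS whose
length is not a codon multiple after phase adjustment triggers a warning and
codon subtyping is skipped for that gene. Percentages in
`summarize_effects()` are shares of *effects*, not SNPs, rounded half-up to
two decimals to match how such tables are printed; a known overall effect
total can be supplied as the denominator when summarising a published subset
of categories.

## LTR retrotransposon dating

The two terminal repeats of an LTR-RT are identical at insertion and diverge
neutrally afterwards, so the insertion age is

$$T = \frac{K}{2r}, \qquad r = 1.4\times10^{-8}\ \text{substitutions
site}^{-1}\,\text{yr}^{-1}\ \text{(default)}.$$

`ltr_divergence()` globally aligns the 5′ and 3′ LTRs (match +1, mismatch
−2, first gap base −4, each further gap base −1 — fixed for determinism; LTR
pairs are near-identical so results are insensitive to these weights),
computes the p-distance over gap-free non-N columns, and applies the
Jukes–Cantor correction $K = -\tfrac34\ln(1 - \tfrac43 p)$ by default (the
raw p-distance is available by flag; $|K - p| \le p^2$ for $p \le 0.05$, so
the choice matters only for old elements). $p \ge 0.75$ saturates the
correction and is an error rather than a silent Inf.

Ages partition into `<0.2My`, `0.2-1My`, `>1My` with boundaries assigned as
$[0, 0.2)$, $[0.2, 1]$, $(1, \infty)$ My so the three labels are a true
partition. An element is centromeric when its midpoint falls in a centromere
interval; enrichment of young elements is a 2×2 Fisher exact test (young vs
older × inside vs outside). A simplified flank test
(`flank_presence_test()`) anchors the element-proximal ends of both flanks
in a second genome by exact 31-mer seeds: flanks mapping adjacently (gap
< 10% of element length) mean the insertion site is empty there; flanks
separated by ≥ 90% of the element length with element-like sequence between
(local identity ≥ 0.9) mean the element is present; repetitive flanks
(> 3 seed hits) or anything else is unresolved. This deliberately replaces a
full synteny pipeline, which is out of scope.

## Centromeric satellite detection

The monomer length of a tandem satellite is estimated as the modal distance
between recurrences of identical k-mers (default k = 13, periods up to
2 kb). A perfect array of period $L$ also peaks at $2L, 3L, \dots$, so among
all periods whose count is within 5% of the maximum the smallest is taken.
This estimator is linear-time and exactly recovers planted periods
50–500 bp, noise-free and at 2–5% substitution rates (tested over 20 seeds).

Array segmentation marks positions whose k-mer recurs at $L \pm 10\%$ as
periodic and joins runs with internal gaps up to `max_gap` (default 5 kb —
pericentromeric arrays are interrupted by transposon insertions); runs
spanning at least `min_copies` × L (default 10) become arrays. The reported
identity is the per-base match fraction between the array and itself shifted
by one monomer, measured over the periodic-covered portion only so that a
non-repetitive spacer joined across `max_gap` does not dilute it; arrays
below `min_identity` (default 0.7) are dropped. Per chromosome, arrays
within `cluster_gap` (default 100 kb) merge into clusters and the cluster
with the greatest total array bp is called as the centromere — one call per
chromosome, with the mean call length reported alongside.

## NB-ARC scanning and NLR pairing

Divergent NLR genes escape homology-based annotation, so the scan translates
the genome in six frames and aligns overlapping amino-acid windows (window =
2 × longest seed, overlap = longest seed, so no hit can straddle two windows
unseen) against each NB-ARC seed protein with BLOSUM62 local alignment (gap
open 11, extend 1). Hits above `min_score` and 80 aa are mapped back to
genomic coordinates and merged when overlapping.

`min_score` is calibrated on a dinucleotide-shuffled null (dimer resampling,
preserving approximate composition): the 99.9th percentile of pooled null
window scores times a 1.25 margin. The margin exists because null maxima
fluctuate by a few points between shuffles while genuine domain hits score
roughly an order of magnitude higher — the calibrated threshold leaves a
fresh shuffled genome with zero loci without costing sensitivity.

`reconcile_nlr_sets()` intersects scan loci with annotation genes (≥ 1 bp on
gene spans): genes with support are `both`, unsupported loci `scan_only`,
unsupported genes `annotation_only`; the three disjoint categories sum to
the union. Head-to-head pairs are adjacent gene pairs with the upstream gene
on '−' and the downstream gene on '+' (both 5′ ends facing the shared
intergenic interval) within `max_dist` — 10 kb by default, a deliberate
choice since the pairing literature prints no distance; it is exposed as a
flag and recorded in outputs. Candidates are paired greedily by ascending
distance, each gene used once. The paired percentage is
$100 \cdot 2|pairs| / |genes|$, rounded half-up to one decimal.

## The synthetic-data generators

The generators exist so every stage has planted truth:

- **Populations**: an ancestral alternate-allele frequency per SNP from
  Beta(0.8, 0.8) (U-shaped, as site-frequency spectra are), group
  frequencies as binomial resamples at depth 200 (weak background
  differentiation), diploids as two independent haploid draws
  (Hardy–Weinberg — the F~ST~ estimator's assumption). A planted sweep
  multiplies the selected group's minor-allele frequency by
  `1 − sweep_diversity_factor` and displaces the other groups' frequency
  towards the opposite allele by `sweep_divergence_shift`. The defaults
  (factor 0.9, shift 0.6, 20 diploids per group, 5 SNPs/kb) were chosen once
  as a strong-but-not-fixed sweep contrast at a realistic resequencing
  density; the source study reports no effect sizes, so these are the
  package's own validation conditions, not claims about rapeseed.
- **LTR elements**: each element is 5′LTR + internal + 3′LTR, the two
  repeats independently mutated at per-site probability `rate × age`, so
  expected pairwise divergence is ≈ 2·rate·age; placement inside a
  centromere interval follows per-age-group probabilities.
- **Satellite chromosome**: random flanks around `n_copies` independently
  mutated monomer copies; with `indel_rate = 0` the array length is exactly
  `n_copies × monomer_len`.
- **Annotation**: genes placed without overlap, planted head-to-head pairs
  at a fixed intergenic distance, all other neighbours separated by at
  least 15 kb so only planted pairs can qualify at the default `max_dist`.

Every generator is a pure function of its parameters including the seed
(identical seed ⇒ byte-identical files). What the generators do *not*
emulate: linkage disequilibrium and coalescent genealogies, demographic
structure, indel/complex variants, nested or truncated repeats, and
annotation errors. Passing the planted-truth suites therefore demonstrates
the *estimators and calling rules* are correct, not that real data meet
their assumptions.

## Validation suite sizes

The test and acceptance suites run on deliberately modest problem sizes: 60
windows × 10 kb × 40 diploids for the sweep scans (20 replicate seeds for
recall; recall is the fraction of planted windows overlapped by a called
region of the correct group), 500 elements per age at 2 kb LTRs for age
recovery (cohort means within 10% of truth), 5000 × 176 bp satellite copies
at 2% substitutions for monomer recovery, and ~30 kb genomes for the NB-ARC
scan calibration. On one CPU the full test suite runs in a few minutes.

## Known limitations

- The sweep scan assumes unstructured groups; kinship or admixture
  correction, and haplotype statistics (XP-EHH, iHS), are out of scope.
- π uses the nominal window length, so sparsely genotyped windows are
  biased towards zero in both groups — the π *ratio* is less affected.
- The effect classifier handles SNPs only (no indels, splice sites or UTR
  subcategories) and takes the first transcript containing a site.
- LTR elements are taken as given coordinates/sequences; structural
  detection (TSDs, TGCA motifs) belongs to the upstream callers.
- The monomer detector reports one fundamental period; higher-order repeat
  structure is not modelled.
- Sensor/executor labelling of pair members requires external clade
  assignments; the pairing operation itself is label-agnostic.
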