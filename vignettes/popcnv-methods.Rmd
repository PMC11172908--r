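---
title: "Copy number variation in structured populations: the popcnv model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy number variation in structured populations: the popcnv model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcnv)
```

## The problem

Resequencing a structured cohort — several local breeds plus commercial
reference populations, say — at moderate depth (~10x) is a standard way to
map copy number variation and to ask which copy number variation regions
(CNVRs) differentiate the populations. `popcnv` implements that analysis
as a small, fully testable pipeline:

1. window the genome and count reads per window (here: simulate them);
2. correct GC bias, rescale each sample so its genome-wide median is the
   diploid state (absolute copy number, CN);
3. call per-sample gain/loss segments by run-length thresholding;
4. aggregate per-sample evidence into population CNVRs, genotype them,
   classify them by loss/gain allele frequencies, and filter on clustering
   quality (silhouette) and length;
5. scan CNVRs with the Vst statistic and flag the empirical top tail as
   selection candidates;
6. annotate CNVRs against genes and QTLs and summarize.

Every stage consumes and produces plain TSV/BED tables with 0-based
half-open coordinates; CNVR identifiers use the 1-based inclusive
`chrom:start-end` locus convention common in the literature.

## Depth model and copy number estimation

Read depth of sample $s$ in window $w$ is modeled (and simulated) as
negative binomial with

$$\mu_{sw} = \bar{c} \cdot \frac{\mathrm{CN}_{sw}}{2} \cdot b(\mathrm{gc}_w),
\qquad \mathrm{Var} = \mu + \phi\,\mu^2,$$

where $\bar{c}$ is the per-window mean coverage, $b$ a unimodal quadratic
GC-bias multiplier and $\phi$ the overdispersion. Defaults: $\bar{c} = 50$
reads/window — with 150 bp reads on 800 bp windows that corresponds to
roughly 9.5x genome coverage, the depth regime this kind of study
operates in; $\phi = 0.003$ (variance ~1.6x Poisson at 50 reads), a mild
overdispersion typical of PCR-free libraries; and $b$ with peak 0.35 and
strength 1.2, i.e. a 0.76-1.0x multiplier across the observed GC range.
A stronger curve mostly manufactures windows whose *post-correction*
copy numbers are twice as noisy as the rest — that is a mappability
problem, which the window mask flag represents instead: masked windows get
erratic simulated depth and are excluded (NA) from every statistic.

GC correction is per-sample median-ratio within 20 equal-width GC bins:
corrected = raw x (global median / bin median). Bins with median zero are
left unchanged and flagged. This removes any smooth multiplicative GC
trend without fitting a curve; the residual depth-GC correlation on
simulated data is below 0.1 for every sample (asserted in the tests).
Absolute copy number is `2 * depth / median(depth)` per sample over
unmasked windows, so a sample's CN is invariant to rescaling its depths
(also asserted as a property test).

## Per-sample calling and its thresholds

Windows with CN <= 1.5 (>= 2.5) seed loss (gain) segments — the midpoints
between integer copy states. Same-kind seeds separated by at most
`max_gap_windows` neutral or masked windows merge; segments spanning fewer
than `min_windows = 2` windows are dropped. We default `max_gap_windows`
to 1 rather than 0: at 50 reads/window a single-copy gain (CN 3) misses a
given window with probability ~0.1, so ungapped runs fragment genuine
multi-window events far more often than a one-window bridge admits false
ones.

At this coverage a lone sample still produces a few dozen chance
two-window calls genome-wide. They are reported (they are what a
per-sample CNV inventory looks like at 10x) but they must not drive
population aggregation — see the next section.

## CNVR construction

A window is a population candidate when the fraction of samples deviating
from diploid (|CN - 2| >= 0.5) strictly exceeds `min_variant_freq = 0.05`.
Applied to raw per-window CN this rule is unusable at realistic coverage:
the per-window deviation probability of a diploid sample is a few percent,
so with 50 samples nearly every window clears a 5% threshold by noise
alone. The builder therefore counts a sample as deviating only where the
window also lies inside one of that sample's calls spanning at least
`min_call_windows = 3` windows. The run-length requirement is what makes
a small population frequency threshold meaningful; the pure-threshold
form remains available (and unit-tested) by omitting the calls.

Flagged runs (gaps <= 1 window bridged) become intervals. Interval
boundaries are then refined on the support profile: terminal windows
backed by fewer than half the interval's median deviating-sample count
are trimmed. Without this, a handful of carriers whose calls overshoot a
variant's edge by one or two windows (expected at these noise levels)
systematically stretches the population boundary. Neighboring intervals
at most `merge_dist_windows = 3` windows apart merge when the Pearson
correlation of their per-sample mean CN vectors is at least
`corr_min = 0.5` — the correlation-merge step that reunites variants
split by masked windows; the distance bound keeps unrelated regions that
happen to share carriers from fusing across clean sequence.

Genotypes: per sample, real CN is the median over the interval's unmasked
windows; integer CN rounds half away from zero and floors at 0 (the copy
number alphabet is {0, 1, 2, 3, 4} throughout — states above 4 are not
distinguished).

Classification uses loss/gain allele frequencies. The default frequency
model is the carrier fraction (samples with CN below / above 2); a
per-allele model (each sample contributes up to 2 loss or gain alleles) is
available via `mode = "allele"`, since published in-text frequencies of
this kind are usually carrier fractions but the convention is rarely
stated. The type predicates are:

* **loss**: 0.05 < loss AF <= 0.95 and gain AF <= 0.01
* **gain**: 0.05 < gain AF < 0.95 and loss AF <= 0.01
* **both**: 0.05 < gain AF < 0.95 and 0.05 < loss AF <= 0.95
* otherwise **none**, excluded.

Note the asymmetry (<= 0.95 for loss, < 0.95 for gain) is deliberate and
preserved exactly; the three informative categories are provably disjoint
and the tests assert this on a dense AF grid. With 50 samples,
`gain AF <= 0.01` tolerates **zero** spurious gain genotypes — one reason
region-median genotypes need to be stable (see the cohort design below).

The silhouette filter treats integer CN states as clusters and computes
the standard silhouette on the 1-D real CNs, with the conventions: one
cluster scores 1.0 (a degenerate pass — a monomorphic region is perfectly
"clustered"), singleton clusters contribute 0, and a point at zero
distance from two clusters contributes 0. CNVRs are kept when type is not
"none", silhouette > 0.6 (strict), and length does not exceed the type
cap: 50 kb for loss and both, 500 kb for gain.

## The Vst scan

For one region and two groups with $n_A$, $n_B$ samples,

$$V_{ST} = \frac{V_T - V_S}{V_T}, \qquad
V_S = \frac{n_A V_A + n_B V_B}{n_A + n_B},$$

with population variances (denominator $n$) of the real-valued genotypes;
$V_T = 0$ returns 0. With variances, the law of total variance bounds
$V_{ST}$ in [0, 1]; a standard-deviation variant is exposed
(`stat = "sd"`) for exploration but loses that guarantee, which is why it
is not the default. Contrasts pool the reference groups (e.g. one local
breed against both commercial breeds as a single sample set). Candidates
are records whose Vst strictly exceeds the contrast's empirical
`1 - q` quantile (type-7 linear interpolation, `q = 0.05`); ties at the
threshold are excluded, so a contrast with all-equal Vst flags nothing.
Note that with $N$ regions a contrast flags roughly $N/20$ records — a
20-region cohort has room for exactly one candidate per contrast, which
constrains how many strongly stratified loci a small validation cohort
can meaningfully plant.

## Annotation and comparison conventions

* Genomic context precedence: exon (>= 1 bp exon overlap) > intron (gene
  body overlap) > intergenic; the three labels partition any CNVR set.
* Gene assignment: intersection / gene length >= 0.5 (inclusive), with a
  CNVR-length denominator available by flag. The gene-length reading is
  the one consistent with assigning fully contained genes.
* QTL overlap is any-overlap (>= 1 bp, half-open coordinates: touching
  intervals do not overlap); summaries count regions with >= 1 hit and
  distinct traits hit.
* Chromosome summary: OLS of per-chromosome CNVR count on chromosome
  length (needs >= 3 chromosomes, otherwise skipped with a warning).
* Cross-study comparison: overlap number counts *this* set's regions
  hitting >= 1 interval of the other set — the only reading consistent
  with published comparison tables where the overlap number can exceed
  the other study's region count; the ratio divides by this set's size
  and is reported rounded to two decimals; overlap length merges each set
  first so nothing is double-counted.

## The synthetic cohort: what it emulates, what it does not

`simulate_study_cohort()` is the package's reference dataset: 5 groups
(RC, T, WZS as "local", YL, LR as "commercial" references) x 10 diploid
samples; four unequal chromosomes (720/560/440/280 kb, 2500 windows of
800 bp); 2% masked windows; 20 planted regions of 8-14 windows
(6.4-11.2 kb, the lower half of a realistic CNV size distribution —
large enough that a region's per-sample median CN is essentially
noise-free at 50 reads/window, which the zero-tolerance classification
thresholds above effectively require). Regions are apportioned to
chromosomes by length, so the count-vs-length regression has signal.

Six regions are modeled on classic breed-stratified loci: a deletion
fixed in RC and absent elsewhere; a duplication fixed in RC but at 50% in
the references; a deletion at 95% in T vs 5% in the references; a 55%
deletion in T; a CN4 duplication at 70% private to WZS; a 15% deletion in
WZS with the references at 35%. The remaining 14 are equal-frequency
background. Exactly one region per local breed (the private fixed
deletion, the 95%-vs-5% deletion, the private CN4 duplication) is marked
`differential = TRUE`: with ~20 CNVRs a top-5% scan can flag only one
record per contrast, so each contrast gets exactly one designed extreme.
Carrier counts are realized exactly as `round(freq x n)` (half up) by
sampling carriers without replacement, so planted frequencies are exact
study conditions rather than expectations.

What the simulation does **not** model: sequence content (GC is a smooth
latent process, masking is random rather than k-mer-derived), breed-level
differences in total CNV load, linkage between regions, multi-allelic
states above CN 4, sex chromosomes, and breakpoints off the window grid.
Passing recovery tests therefore demonstrate that the *computational*
chain is correct and well-calibrated at realistic depth and noise — not
that any particular biological cohort would yield the same error rates.

## Numerical choices and degenerate inputs

* Rounding of genotypes is half-away-from-zero (symmetric around the
  diploid state); carrier-count realization is half-up.
* Vst of a zero-variance pooled vector is 0; silhouette of a single
  cluster is 1; correlation-merge is skipped when either interval's mean
  CN vector is constant (correlation undefined -> no merge).
* An all-zero sample is a hard error naming the sample (a normalization
  denominator of zero is unrecoverable); a fully masked interval is an
  error at genotyping.
* GC bins with zero median leave their windows uncorrected and are
  reported via an attribute rather than silently rescaling zeros.
* Per-stage seeds are derived from the master seed by hashing the stage
  name (FNV-1a), so stages rerun standalone reproduce the pipeline run
  exactly; all outputs are byte-identical under a fixed seed.

## Problem sizes used in validation

The package's own test suite exercises: the reference cohort above
(50 samples x 2500 windows, 20 regions) for end-to-end recovery; 300
random genotype-vector pairs (up to 60 pooled samples) against a
brute-force Vst oracle; a 101 x 101 allele-frequency grid against an
independently coded classifier; 100 random interval sets (up to ~60
intervals each) against all-pairs brute-force overlap; and the demo
pipeline (2 x 2 Mb chromosomes, 5 x 4 samples) twice for byte-identical
reproducibility. These sizes keep the full suite under a minute on one
CPU while leaving every statistic's sampling error far from the asserted
margins.

## Known limitations

* Boundaries are window-resolution; no sub-window breakpoint refinement.
* The correlation threshold standing in for "significant correlation
  between adjacent windows" is a fixed `corr_min`, not a formal test.
* The caller's thresholds (1.5/2.5) assume the diploid rescaling is
  correct; a genome where more than half the windows are copy-variable in
  a sample would shift its median and bias every call.
* At 50 reads/window, single-copy gains are intrinsically the hardest
  state: roughly 9% per-window miss probability, which is why per-carrier
  (as opposed to per-region) boundary accuracy is not asserted beyond a
  majority-of-carriers criterion.
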