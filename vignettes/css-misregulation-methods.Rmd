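---
title: "Methods: transcriptional misregulation analysis for chromosome substitution strains"
author: "cssmisreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptional misregulation analysis for chromosome substitution strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cssmisreg)
```

## Scientific setting

A chromosome substitution strain (CSS) carries one chromosome — or a
sub-chromosomal interval — from a donor (sub)species on an otherwise pure
host genetic background. When the donor's cis-regulatory elements meet the
host's trans-acting factors, genes inside the substituted region can be
misexpressed, and that primary misregulation can secondarily propagate to
the rest of the genome. Distinguishing the two modes per transcript is the
core analytical task this package implements:

* a **cis-regulated** transcript simply follows the donor allele: its level
  in the CSS converges to the donor strain's level;
* an **incompatibility-type** transcript matches *neither* parent: the
  donor cis-element is misread by the host trans environment.

The surrounding pipeline covers everything such a comparison needs on a
short-oligo microarray platform: masking probe sets whose donor-genome
polymorphisms would corrupt the signal, filtering undefined boundary
regions, calling differential expression, testing whether fold-change
dispersion is chromosome-specific, comparing the CSS against both parents,
typing F1 individuals as restored or non-restored by PCA, and mapping the
modifier locus in a backcross.

## The synthetic study

Real deposited array data are not required: `generateGenome()`,
`sampleArchitecture()`, `generateExpressionStudy()`,
`generateProbeAnnotation()` and `generateBackcross()` build a study with
known ground truth whose statistical structure mirrors the emulated design.
Defaults were chosen once, to match the design being emulated, and are not
adjusted per analysis:

* **Genome**: 19 autosomes plus X, 500 gene positions per chromosome
  (~10,000 probe sets). This reproduces the scale that matters most for the
  rank-based dispersion test: roughly 300–450 expressed X-linked probe sets
  after filtering, the regime in which a ~15% contaminated X is clearly
  separable from the autosomal bulk. A pilot power consideration drove this
  choice: the Ansari–Bradley test has low power against a small
  contaminated fraction when only a few dozen X transcripts are available.
* **Design**: 3 replicates per strain at 5 and 7 days postpartum (dpp);
  intensities are linear-scale, modelled as `2^(baseline + offset + noise)`
  with baseline `N(6, 2)` in log2 units (spanning the 10/100/1000 intensity
  strata) and replicate noise sd 0.25 log2 — typical microarray replicate
  scatter.
* **Architecture**: 10% cis-divergent (effects `N(0, 0.8)` log2), 10%
  trans-incompatible, 10% cascade targets; incompatibility magnitudes are a
  shifted folded normal `1 + |N(0, 0.5)|` with a Bernoulli sign, negative
  with probability 0.7. The asymmetry (down-bias) is a qualitative feature
  of the emulated biology; no quantitative effect-size law is published, so
  these are calibration knobs, documented here once.
* **Cascade**: at the later age (7 dpp) cascade-target genes on any
  chromosome acquire incompatibility-type shifts in substitution strains
  only, reproducing the genome-wide spread of misregulation between the two
  time points. The host and the donor strain never cascade.
* **Probe polymorphism**: inside donor-derived intervals each probe is
  polymorphic with rate 0.35 (a polymorphic probe is unidentified in the
  donor genome with probability 0.3, otherwise identified-but-mismatched);
  outside, the rate is 0.02. The donor rate is set so that roughly a
  quarter of donor-region probe sets exceed the score-10 threshold,
  matching the order of the reported exclusion fraction for the X.
* **Backcross**: 314 progeny, 80 markers on one ~195 Mb chromosome at a
  uniform 0.5 cM/Mb, one planted QTL at 64.5 Mb with an additive effect of
  1 residual sd. Genotypes follow a Markov walk with Haldane recombination
  fractions; the QTL is simulated as an unobserved locus inside the walk so
  its linkage to flanking markers is exact.

What the generator does **not** emulate: probe-level (CEL) data and RMA
summarisation (intensities are generated at the probe-set level);
cell-type composition shifts between ages; correlated co-regulation
(gene effects are independent); array batch effects. Passing tests
therefore demonstrate the correctness and calibration of the statistical
machinery under the stated generative model, not robustness to artefacts
absent from it.

## Probe filtering

The polymorphism score of a probe set with `t` probes, `i` identified in
the donor genome and `p` perfectly matched is, by default,

\[ s = 3\,(t - i) + 2\,(i - p), \]

monotone in both the unidentified and the mismatched probe count; a probe
set is *conserved* iff `s <= 10`. The exact published classifier matrix is
not reproduced in text form anywhere, so the linear rule with the printed
threshold is the default and any score matrix can be supplied
(`scoreTable` argument) — the structure (monotone lookup, threshold 10) is
what the filter relies on.

Region filtering removes, in order of attribution: unknown-chromosome
probe sets, Y-linked probe sets, probe sets in a boundary (undefined
genotype) interval of either compared strain, and *polymorphic* probe sets
inside a donor-derived interval of either compared strain. Polymorphic
probe sets outside donor regions are retained: there the host allele is
the one being measured, and the donor-genome mismatch is irrelevant. This
per-comparison donor-region rule (rather than genome-wide exclusion)
follows the treatment of heterozygous-chromosome comparisons, where only
the substituted chromosome's polymorphic probe sets are dropped.

The intensity filter keeps a probe set iff its replicate-mean linear
intensity strictly exceeds 10 in at least one of the two compared strains.
The replicate mean is the default reading of "paired strains"; a
per-sample variant is available (`perSample = TRUE`). Coordinates are
1-based inclusive bp throughout, intervals closed.

## Differential expression

All statistics run on `log2(intensity)`. For a test/reference pair the
per-gene pooled variance \(s_g^2\) (df \(d_g = n_1 + n_2 - 2\)) is shrunk
toward an ensemble prior \((d_0, s_0^2)\):

\[ \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
   t_g = \frac{\bar x_g - \bar y_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}}, \]

with \(t_g\) referred to a t distribution on \(d_0 + d_g\) df. The prior
is estimated by moment matching on log variances: the log of a scaled
chi-square has digamma/trigamma moments, so the spread of
\(\log s_g^2\) in excess of \(\mathrm{trigamma}(d_g/2)\) determines
\(d_0\) (via the inverse trigamma, solved by Newton iteration) and the
location determines \(s_0^2\). When the observed spread does not exceed
the sampling spread, \(d_0 = \infty\) and all genes share the arithmetic
mean variance. `priorDf = 0` disables moderation and reproduces the
ordinary pooled-variance two-sample t exactly — the configured fallback.
This estimator class is standard empirical-Bayes practice; the tests
cross-check it against an independent implementation (limma) and against a
direct per-gene t-test, and verify its type-I calibration on replicated
null studies from the generator.

P-values are adjusted with the Benjamini–Hochberg step-up rule
(`stats::p.adjust`, validated against the textbook formula in tests).
A transcript is **significant** iff its adjusted p is below 0.05 *and* its
linear fold change is at least 1.50 in either direction
(`|log2 FC| >= log2 1.5`); the thresholds are arguments everywhere.
Importantly, the BH family is the *filtered* probe universe of the
comparison, so filtering precedes testing.

Frequency tables report, per chromosome (with an optional proximal/distal
X split at the substitution breakpoint, default 86,497,454 bp), the
expressed count and the up/down counts with percentages rounded to two
decimals. Two whole-autosome aggregation conventions are exposed:
`pooled` (summed counts over summed expressed) and `meanPct` (unweighted
mean of the 19 per-chromosome percentages). Both are reported because
published whole-autosome summary percentages accompanying such tables
follow the unweighted-mean convention, which weights small chromosomes
equally, while the pooled convention answers "what fraction of autosomal
transcripts changed". The two differ in the second digit.

## Dispersion analysis

Whether X-linked fold changes are more *dispersed* than autosomal ones is
tested with the Ansari–Bradley rank test on group-centred data: each
group's median is subtracted first (mean-centring is a config option;
per-chromosome centring is deliberately not the default, since the
comparison groups are chromosome classes). Over the pooled sample of size
N, observation with rank r scores \(\min(r, N+1-r)\) (midranks under
ties); the statistic is the score sum of the first group. The null is
computed by full enumeration over all assignments whenever the smaller
group has at most `exactMaxN = 10` members (and at most 5·10^5
combinations), which remains valid under ties; otherwise a normal
approximation with tie-corrected variance is used. P-values are two-sided
and floored only by numeric underflow — no display floor such as 1e-16 is
imposed. Degenerate input (all values identical) warns and returns p = 1.

The stratified variant repeats the test inside raw-intensity bands
(default edges 10/100/1000, bands `(10,100]`, `(100,1000]`, `(1000,Inf)`)
to show a dispersion difference is not an expression-level artefact; a
band in which either group has fewer than two members is reported as
skipped rather than dropped silently — with the banding taken from the
reference strain's mean intensity.

## Regulatory classification

`correlationComparison()` computes Pearson correlations of the CSS's
log-scale group means with each parent over a transcript subset and
compares them via Fisher's z: \(z_i = \mathrm{atanh}(r_i)\), statistic
\((z_{donor} - z_{host}) / \sqrt{2/(n-3)}\), one-sided p for the
alternative that the CSS tracks the donor. The two correlations share the
CSS vector, so treating them as independent is an approximation — the
approximation the emulated analysis itself uses; a permutation oracle in
the test suite confirms the p-values agree within Monte-Carlo error in
this regime.

`classifyRegulatoryType()` types each significant donor-region transcript
by the linear ratio of CSS to donor replicate-mean intensities:
**cis_regulated** iff `1/band < ratio < band` with band 1.5 and *strict*
inequalities (a ratio of exactly 1.5 does not "converge to less than
1.5-fold"), else **incompatibility**. Group means, not per-replicate
values, enter the ratio. `overlapAnalysis()` intersects significant sets
from two comparisons and reports the share of one set recovered in the
other plus the genomic breakdown of the common set.

## Sample structure

`pcaSamples()` takes principal components of the gene-centred log2 matrix
with samples as observations. Scores are deterministic up to sign; signs
are fixed by making the first nonzero gene loading of each component
non-negative. `assignRestoration()` types F1 individuals by
nearest-centroid on PC1 only, with a dead-band margin (default 0) inside
which individuals are conservatively called non-restored. The margin rule
is a stand-in for a verbal "relatively close to the host cluster"
criterion — no numeric rule is published — and is therefore a config
option, not a claim. `topKTable()` ranks significant transcripts by
|log2 FC| with ties broken by adjusted p and then probe id, and juxtaposes
the same transcripts' fold changes in other comparisons (e.g. a restored
strain, where they should shrink toward zero).

## QTL mapping

For a backcross (genotypes 0 = host homozygote, 1 = heterozygote), the
single-marker LOD is \((n/2)\log_{10}(RSS_0/RSS_1)\) from regressing the
trait on the genotype. Haley–Knott interval mapping scans a grid (1 Mb
walk speed plus all marker positions) and regresses the trait on the
expected heterozygosity computed from the nearest informative flanking
markers via Haldane recombination fractions
\(r(d) = \tfrac12(1 - e^{-2d/100})\); progeny with one informative flank
use that flank alone, progeny with none contribute 0.5. At a fully
genotyped marker the expected heterozygosity equals the observed genotype,
so the HK profile coincides with the single-marker scan there — an
invariant the tests enforce to 1e-9. Genetic positions default to a
uniform 0.5 cM/Mb when only physical positions are available; the rate is
explicit and overridable. Significance thresholds come from trait
permutation (default 1000 permutations), not theoretical curves.

## Numerical choices and degenerate inputs

* Inverse trigamma by damped Newton iteration, convergence 1e-10.
* Zero-variance genes are excluded from prior estimation; a zero standard
  error yields t = 0 (identical groups give p = 1, not NaN).
* Exact AB enumeration compares score sums with a 1e-9 absolute guard so
  midrank ties are not split by floating-point noise.
* `findInterval` plus per-progeny nearest-informative-flank indices make
  interval mapping O(grid × progeny); contradictory flanks at zero genetic
  distance (inconsistent data) fall back to probability 0.5.
* Writers emit percentages with exactly two decimals; all tabular output
  is TSV (UTF-8, '.' decimal); genotype CSV accepts {0, 1, NA}.
* Fold-change thresholding is done on the linear scale; intensities are
  stored linear and modelled in log2, reconciling the linear-intensity
  filter (">10") with log-scale statistics.

## Problem sizes in the test suite

The suite exercises each property at the smallest size that is
statistically meaningful: enumeration oracles at group sizes ≤ 8,
calibration on 500 replicated ~100-gene null studies, classification
recovery on ~600-gene genomes, QTL recovery on 20 replicated 314-progeny
crosses, and two full pipeline runs at reduced genome size for
byte-determinism. The default pipeline scale (10,000 probe sets) is used
where power matters.

## Known limitations

* The moderated t assumes roughly exchangeable gene variances; strong
  variance–intensity trends would call for a covariate-dependent prior,
  which is not implemented.
* The Fisher z comparison ignores the dependence induced by the shared
  CSS vector; a dependent-correlations (Steiger-type) variant would be
  more exact but is not the emulated procedure.
* Restoration typing uses PC1 only; profiles whose restoration is
  orthogonal to the host/CSS axis would be mistyped.
* Interval mapping fits a single-QTL model; linked QTL inflate and shift
  peaks, as in any single-scan analysis.
* The generator's independence assumptions (gene effects, probes,
  replicates) understate the correlation structure of real arrays, so
  real-data p-values will be less well calibrated than the synthetic
  checks suggest.
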