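# cssmisreg

Analysis of transcriptional misregulation in chromosome substitution
strains (CSS) — inbred strains in which one chromosome, or a
sub-chromosomal interval, is replaced by the counterpart from a diverged
donor (sub)species. When donor *cis*-regulatory elements meet host
*trans*-acting factors, genes inside the substituted region can be
misexpressed, and that misregulation can spread genome-wide over
developmental time. This package implements, as reusable tested R
functions, the complete expression-analysis pipeline such a study needs,
together with a synthetic-data generator with known ground truth so every
stage can be validated without array downloads.

The pipeline, per stage:

1. **Probe filtering** — probe sets are scored for polymorphism against the
   donor genome from the number of probes identified (`i`) and perfectly
   matched (`p`) out of `t`: `score = 3(t−i) + 2(i−p)`, conserved iff
   `score ≤ 10`. Polymorphic probe sets inside donor-derived intervals,
   boundary-region, unknown-chromosome and Y-linked probe sets are removed;
   then an intensity filter keeps probe sets with replicate-mean linear
   intensity > 10 in at least one compared strain.
2. **Differential expression** — empirical-Bayes moderated t-test on log2
   intensities (per-gene variance `s²_g` shrunk toward a moment-matched
   prior `(d₀, s₀²)`; posterior `(d₀s₀² + d_g s²_g)/(d₀+d_g)`), BH-FDR
   adjustment, and calling at adjusted p < 0.05 with linear fold change
   ≥ 1.50; per-chromosome frequency tables with an optional
   proximal/distal X split.
3. **Dispersion analysis** — Ansari–Bradley rank test on group-centred
   fold changes (exact by full enumeration for small groups, tie-corrected
   normal approximation otherwise), overall and stratified by raw
   intensity (10/100/1000).
4. **Regulatory classification** — Pearson correlation of the CSS with
   each parent compared by Fisher's z; each misexpressed donor-region
   transcript typed *cis-regulated* (CSS/donor ratio strictly inside
   [1/1.5, 1.5]) or *incompatibility* (matches neither parent); DE-set
   overlap between strains.
5. **Sample structure** — PCA of expression profiles, restored /
   non-restored typing of F1 individuals by nearest centroid on PC1, and
   top-k fold-change ranking tables across strains.
6. **QTL mapping** — single-marker regression LOD
   `(n/2)·log10(RSS₀/RSS₁)` and Haley–Knott interval mapping at 1 Mb walk
   speed with Haldane recombination fractions
   `r(d) = ½(1 − e^(−2d/100))`, plus permutation thresholds.

Data live in Bioconductor containers: a `CSSExperiment`
(SummarizedExperiment with linear intensities, strain/age/replicate
metadata and genomic annotation), `StrainModel` (GRanges-backed donor and
boundary intervals) and `BackcrossData` (genotypes, marker map, traits).

## Worked example

```r
library(cssmisreg)

# polymorphism scoring: fully conserved, borderline, fully polymorphic
polymorphismScore(c(11, 11, 0), c(11, 5, 0))
#> [1]  0 12 33

# simulate the full study (19 autosomes + X, 500 genes each, 3 replicates
# at 5 and 7 dpp, whole-X and distal-X substitution strains) and run
# every analysis stage
res <- runPipeline(runConfig(seed = 1), outDir = "pipeline_out")

tab <- res$freq$cssX_5dpp
tab[tab$chrom %in% c("1", "3", "X"), ]
#>  chrom expressed up upPct down downPct
#>      1       467  0  0.00    0    0.00
#>      3       451  0  0.00    0    0.00
#>      X       317 10  3.15   23    7.26
```

At 5 dpp, misexpression is confined to the substituted X chromosome
(3.15% up, 7.26% down, versus essentially nothing on the autosomes). By
7 dpp the cascade has spread it genome-wide:

```r
autosomeAggregate(res$freq$cssX_7dpp, "pooled")
#>  expressed  up upPct down downPct
#>       8715 304  3.49  602    6.91

res$dispersion[res$dispersion$stratum == "all", ]
#>  age stratum   n1  n2 statistic            p skipped
#>    5     all 8681 317  19622000 7.772447e-05   FALSE
#>    7     all 8715 318  19756907 1.642672e-03   FALSE
```

The Ansari–Bradley test confirms that X-linked fold changes are
significantly over-dispersed relative to autosomes at both ages. The
downstream stages recover the planted structure — the F1 restoration
typing finds exactly the 3 simulated restored individuals among 8, and
interval mapping localises the planted chromosome-1 QTL (64.5 Mb):

```r
table(res$restoration$type)
#> non_restored     restored
#>            5            3

lodPeak(res$lodHK)
#> $positionBp
#> [1] 63037975
#>
#> $lod
#> [1] 18.19641
```

Every stage also writes a TSV into `pipeline_out/` (DE call tables,
frequency tables, dispersion results, typing summaries, PCA scores, LOD
profiles) plus a `manifest.txt` recording the seed and thresholds. A thin
command-line wrapper is installed at
`system.file("scripts", "run_pipeline.R", package = "cssmisreg")`.

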