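# File formats

All tabular files are TSV (tab-separated, header row, UTF-8, '.' decimal)
unless noted. Coordinates are 1-based inclusive bp. Percentages are written
with exactly two decimals.

## Expression study (three files)

`readExpression()` / `writeExpression()`

| file | columns |
|---|---|
| intensity matrix | `probeSet`, then one numeric column per sample (linear-scale intensities, > 0) |
| sample metadata | `sample`, `strain`, `age` (days postpartum), `replicate` |
| probe annotation | `probeSet`, `chrom`, `position` (bp), optional `nProbes`, `nIdentified`, `nPerfect`, `polyScore`, `status` |

Probe ids must be unique; metadata sample ids must match the intensity
columns exactly. Probe counts must satisfy
`0 <= nPerfect <= nIdentified <= nProbes`.

## Strain genome composition

`readStrainComposition()` / `writeStrainComposition()` — one row per
interval:

`strain`, `chrom`, `start`, `end`, `zone` (`donor` | `boundary`),
`zygosity` (`homozygous` | `heterozygous`, optional, default homozygous).

Donor intervals must not overlap within a strain and chromosome. Strains
without donor material (pure hosts) may be omitted from the file and added
via the `hostStrains` argument.

## Backcross data

`readBackcross()` / `writeBackcross()`

| file | format |
|---|---|
| genotypes | CSV: `progeny`, one column per marker, values `0` (host homozygote), `1` (heterozygote) or `NA` |
| marker map | TSV: `marker`, `chrom`, `bp`, `cM`, sorted by position |
| traits | CSV: `progeny`, one numeric column per trait |

Progeny ids must agree between the genotype and trait files.

## Outputs

`runPipeline()` writes per stage: DE call tables (`de_*.tsv`), frequency
tables (`freq_*.tsv`, percentages at two decimals), filter reports,
dispersion results (`dispersion.tsv`: age, stratum, group sizes,
statistic, p, skipped flag), correlation comparison, regulatory typing and
its summary, overlap summary and breakdown, PCA scores, restoration
calls, top-k table, LOD profiles (`lod_single.tsv`, `lod_hk.tsv`:
position bp, cM, LOD) and a plain-text `manifest.txt` (package version,
seed, thresholds, per-stage row counts).
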