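# redoxomics

Multiplexed TMT proteomics, cysteine thiol-oxidation occupancy and
lipidomics integration for nitrogen-limited *Rhodotorula toruloides*.

## The problem

Oleaginous yeasts remodel their proteome and lipidome when nitrogen runs
out: carbon is rerouted into storage lipids (TG/DG) while regulatory
proteins are switched by post-translational modifications, including
reversible oxidation of cysteine thiols and phosphorylation. Measuring
those layers together takes a multiplexed design -- two TMT-18 plexes per
assay with shared 24 h bridge channels for batch correction, pooled
total-thiol (-NEM) reference channels for occupancy, and skipped "empty"
channels -- and a normalization chain that keeps the layers comparable.
This package implements that chain as a tested, reusable library for
analysts working with PSM-level reporter-intensity exports and lipid
peak-height tables.

## What it computes

* **Global proteomics** — protein rollup by summation of FDR-passing
  peptide reporter intensities, log2, bridge-channel batch correction,
  channel median centering.
* **PTM sites (redox / phospho)** — site-key aggregation (composite keys
  like `RT_0001_S512;T513` stay distinct), channel-loading scaling
  against the global peptide data, median centering, batch correction,
  and per-condition protein-abundance subtraction.
* **% occupancy** — for a cysteine site and condition,
  `100 * mean(thiol-ox channels) / mean(total-thiol pool duplicates)` on
  loading-scaled linear intensities; peptide ionization efficiency
  cancels in the ratio.
* **Lipidomics** — missing-as-NA handling, probabilistic quotient
  normalization (`value / median(value / reference)` per sample), subclass
  sums, row z-scaling for heatmaps.
* **Differential statistics** — empirical-Bayes moderated t-tests
  (method-of-moments prior on log s², moderated variance
  `(d0·s0² + df·s²)/(d0 + df)`), the factorial model
  `~ Nitrogen + Time + Nitrogen:Time`, a ≥2-biological-replicate filter,
  Benjamini–Hochberg adjustment and Storey q-values.
* **Enrichment & integration** — exact hypergeometric ORA within a
  declared universe, rank-based (Wilcoxon) lipid set enrichment, and
  Pearson correlation of oxidized-site condition profiles against TG/DG
  subclass trajectories with the r > 0.80, |log2FC| ≥ 0.8 selection rule.
* **Synthetic studies** — `simulateStudy()` generates full designs, PSM
  tables and lipid tables with known ground truth (occupancies,
  stoichiometries, loadings, batch offsets), so the whole pipeline is
  testable without raw mass-spectrometry downloads.

## Worked example

```r
library(redoxomics)
cfg <- simConfig(n_proteins = 100L, n_cys_sites = 150L,
                 n_phospho_sites = 100L, seed = 1)
res <- runAll(cfg, outdir = "demo_run")
res$manifest
#>           stage n_in n_out dropped note
#> 1      simulate    0   630    -630
#> 2  global_quant  600   100     500
#> 3   redox_quant  300   150     150
#> 4     occupancy  900   900       0
#> 5 phospho_quant  200   100     100
#> 6   lipid_quant  206   206       0
#> 7    diff_stats  556  1630   -1074
#> 8     integrate  150     0     150

head(res$occupancy, 4)
#>      site_key condition mean_percent_oxidation n_channels flagged
#> 1 RT_0001_C10   high_24              10.758280          2   FALSE
#> 2 RT_0001_C20   high_24               9.488645          2   FALSE
#> 3 RT_0002_C10   high_24               9.458981          2   FALSE
#> 4 RT_0002_C20   high_24               8.376104          2   FALSE
```

The manifest records, per stage, how many rows went in and came out
(`global_quant` turns 600 PSM rows into 100 proteins; `occupancy` reports
one row per site-condition cell). Occupancies land in the 5–30% range the
generator draws baseline oxidation from — e.g. site `RT_0001_C10` is
~10.8% oxidized at 24 h under high nitrogen. Time-matched moderated
tests then rank sites by adjusted p:

```r
d <- res$diffs$redox
head(d[order(d$adj_p), c("feature_id", "contrast", "log2FC", "adj_p")], 3)
#>      feature_id          contrast    log2FC        adj_p
#> 219 RT_0035_C10 low_48 vs high_48 -1.514879 2.492119e-32
#> 366 RT_0033_C20 low_72 vs high_72 -1.468638 4.378522e-32
#> 410 RT_0060_C10 low_72 vs high_72 -1.458147 6.366111e-32
```

These are the generator's planted ±1 log2 occupancy shifts, recovered
after protein adjustment. `res$correlations` and `res$selected_sites`
hold the TG/DG integration; with the default generator (nitrogen effects,
no site-lipid coupling) the r > 0.80 conjunction typically selects
nothing, which is the correct null behaviour.

Matrices print as S4 containers that track their provenance:

```r
res$proteins
#> OmicsMatrix: 100 features x 28 channels [log2]
#>   steps: rollup_protein -> log2_transform -> bridge_batch_correct -> median_center_channels
#>   channels: bridge=12, sample=12, total_thiol_pool=4
```

## Documentation

The methods vignette (`vignettes/redoxomics-methods.Rmd`) describes the
models and their assumptions, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate,
and the package's numerical conventions.
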