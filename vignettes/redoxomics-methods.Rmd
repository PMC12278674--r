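---
title: "Models and methods behind redoxomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind redoxomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxomics)
```

# The experimental system

`redoxomics` implements the quantitative analysis chain for a multi-omics
study of the oleaginous yeast *Rhodotorula toruloides* grown under
nitrogen-rich and nitrogen-limited conditions (a 2 x 3 grid: high/low
nitrogen x 24/48/72 h, three biological replicates). Three proteomics
readouts come from the same TMT-18 labelled material, split after
labelling: unenriched aliquots measure global protein abundance,
resin-assisted capture enriches reversibly oxidized cysteine peptides
(redox), and IMAC enriches phosphopeptides. The matched lipidome is
measured separately as peak heights per lipid species.

Two design features of the TMT layout carry the normalization strategy:

* **Bridge channels.** The six 24 h samples are split into technical
  replicates and labelled in both plexes. Their cross-plex agreement
  defines the between-plex (batch) offsets.
* **Pooled total-thiol channels.** Each redox plex carries duplicate
  channels of a pooled, fully reduced (-NEM omitted) sample. The ratio of
  a site's oxidized (+NEM) signal to this total-thiol reference gives
  percent occupancy.
* **Empty channels.** Two reporter channels per plex are skipped to keep
  isotope impurity bleed-through away from the low-intensity thiol
  oxidation channels; they carry no sample and are excluded from all
  quantitative operations.

# Normalization chains

Global proteomics: **rollup** (sum of FDR-passing peptide reporter
intensities per protein; missing values are skipped, never zero-filled) ->
**log2** -> **bridge batch correction** -> **channel median centering**.
Each container records its applied steps and refuses to run a step twice
or out of its scale precondition.

PTM sites: **aggregate** (sum per site key) -> **log2** ->
**channel-loading scaling** -> **median centering** -> **batch
correction** -> **per-condition protein subtraction**. Composite site keys
such as `RT_0001_S512;T513` (ambiguous localization) are aggregated only
with the identical composite and kept distinct from their single-residue
keys.

## Channel-loading scaling

PTM enrichment intensities inherit the per-channel loading of the shared
labelled material, so loadings are estimated from the *global peptide*
matrix (log2, not batch-corrected) and transferred to the PTM channels of
the same physical plex and reporter label. The estimator references each
peptide to its own median across channels and takes the per-channel
median of those deviations, centered to a median offset of zero. The
reference-profile step matters: peptide abundances span several log2
units, and raw per-channel medians inherit that spread as channel-level
noise (offset errors near 0.05-0.1 log2 at a few hundred peptides), which
propagates directly into occupancy estimates. Referencing each peptide to
itself removes the spread, and the estimate is exact for a uniformly
over-loaded channel at zero noise. A median across channels also keeps
the estimator insensitive to differential features so long as they do not
dominate a channel.

## Bridge batch correction

For each feature, the offset of a plex is the mean of the feature's
bridge-channel values in that plex minus the mean over all plexes' bridge
channels; subtracting the offset from every channel of the plex aligns
plexes feature-by-feature while leaving all within-plex differences
untouched. Features with no observed bridge value in a plex fall back to
the plex-median offset across features. A `method = "median"` variant
(per-feature, per-plex median alignment) covers designs without bridges.

## Protein subtraction

Site-level fold changes confound PTM stoichiometry with protein
abundance. After full normalization, the mean normalized abundance of the
site's parent protein per condition is subtracted from the site values of
that condition. Orphan sites whose parent protein was not quantified are
left unadjusted and flagged rather than dropped. A practical limit: with
balanced +-1 log2 protein effects on half the proteome, channel median
centering leaves a small condition-dependent constant (a quantile-shift
artifact that scales as 1 / sqrt(number of features)); at the study's
identification depth (~2,800 proteins, ~3,000 quantified cysteine sites)
the residual mean |site log2FC| is ~0.03-0.05 at zero noise and ~0.11 at
CV 0.1.

## Percent occupancy

For each cysteine site and condition, occupancy is

    100 * mean(thiol-ox channel intensities) / mean(total-thiol pool duplicates)

computed on loading-scaled *linear* intensities, before log2 and before
protein subtraction; "normalized raw intensities" admits more than one
reading, and the loading-corrected, un-logged one is used here. Ratios are
formed within each plex and then averaged across the plexes in which the
condition appears (the 24 h bridges appear in both), so any residual plex
factor cancels inside each ratio. Peptide ionization efficiency cancels
between numerator and denominator, which is what makes the percentage
interpretable across sites. Values above 100% can arise under measurement
noise and are retained but flagged, preserving the distribution shape for
population summaries.

# Lipidomics

Missing peak heights (blanks or zeros) are masked at load. Following the
convention of treating missing values as 1 before log-transformation,
probabilistic quotient normalization runs on linear intensities (the
standard Dieterle formulation): the reference spectrum is the per-lipid
median over samples, each sample's dilution factor is the median quotient
against the reference, and originally missing cells are restored to
missing afterwards -- the mask is bit-identical across the operation.
log2 follows PQN; running PQN on log values instead would normalize
ratios of logs, which is not the dilution model. Subclass summaries sum
linear intensities (missing contributes zero), and heatmap scaling is the
usual row z-score with an n-1 denominator; constant rows are an error
rather than silent zeros.

# Differential statistics

Features must be observed in at least two biological replicates of a
condition in the tested contrast (technical replicates collapse by sample
first, so a bridge sample measured in both plexes counts once). Two-group
tests are time-matched (low vs high nitrogen at the same timepoint) on
log2 data, with empirical-Bayes variance moderation: a scaled
inverse-chi-square prior is fitted to the per-feature variances by method
of moments on log s^2 (digamma/trigamma corrections; the prior degrees of
freedom solve a trigamma equation by Newton iteration to |delta| < 1e-8).
When the spread of log s^2 does not exceed its theoretical sampling
variance the prior degrees of freedom are infinite and all variances
shrink to the common mean. The moderated t has d0 + df degrees of
freedom; with no prior the test is the ordinary Student t, and d0 = 0
reproduces it exactly.

The factorial model `~ Nitrogen + Time + Nitrogen:Time` codes nitrogen
0 = high / 1 = low and time numerically in hours centered at 24 (a
categorical-time option exists; the numeric coding reads the interaction
as a per-hour divergence rate, which matches the monotone trajectories
the design can see with three timepoints). Per-feature OLS coefficient
standard errors are moderated with the shared prior. Exact fits (zero
residual variance at zero noise) use the degenerate convention t = 0,
p = 1 for zero coefficients. Multiple testing uses Benjamini-Hochberg
throughout; Storey q-values with fixed lambda = 0.5 are reported alongside
for enrichment tables.

# Enrichment and integration

Over-representation uses the exact hypergeometric upper tail within a
declared universe (for lipids, all identified species; for sites, the
quantified-site universe mapped to parent proteins), with sets of fewer
than two in-universe members skipped. The rank-based lipid set test is a
two-sided Wilcoxon rank-sum of member log2 fold changes against
non-members: exact by enumeration up to 12 scored features and a normal
approximation with continuity correction beyond. Enrichment tables are
reported at q <= 0.2 and adjusted p <= 0.05 jointly.

Integration correlates per-condition mean abundances of oxidized cysteine
sites (protein-adjusted by default; the unadjusted matrix is available)
with per-condition summed lipid subclass intensities over the six
condition cells (Pearson, n = 6). Sites with r > 0.80 against **both** TG
and DG (read as a conjunction; `mode = "any"` gives the union) and
|log2FC| >= 0.8 for the factorial nitrogen coefficient feed the
over-representation step.

# The synthetic-data generator

`simulateStudy()` emulates the measurement process with known ground
truth so every downstream stage is testable without raw data: protein
baselines ~ Normal(20, 2) log2 units with nitrogen effects on a
configurable differential fraction (half up, half down); fixed log-normal
peptide ionization efficiencies; channel intensities proportional to
2^(protein log2) x efficiency x channel loading x plex batch factor with
multiplicative log-normal noise parameterized by a single CV; redox +NEM
channels proportional to occupancy pi times protein level with pooled
total-thiol channels carrying the unweighted mean of the pi = 1 signal
over all 18 samples; phospho channels proportional to stoichiometry times
protein level; empty channels at zero. Lipid levels follow the subclass
composition of the identified lipidome (206 species; TG/DG rising and
phospholipids falling over time by default) with a global low-intensity
dropout emulating blank cells. Defaults: noise CV 0.1, loading sdlog 0.2,
plex-2 batch offset +0.5 log2, baseline occupancy Uniform(0.05, 0.3),
stoichiometry Uniform(0.1, 0.9), 5% decoy PSMs failing FDR.

What the generator deliberately does not model: spectral-level effects
(isotope impurity bleed-through, co-isolation interference -- the empty
channels exist as a class but their rationale is not simulated),
enrichment losses in RAC/IMAC (treated as lossless), peptide-level
missingness mechanisms in proteomics (the pipeline's >= 2-replicate filter
is the guard used instead of a censoring model), and protein time trends
(nitrogen-only effects by default). Passing recovery tests therefore
demonstrates correctness of the arithmetic and the normalization
contracts, not robustness to those unmodelled artifacts in real spectra.

# Numerical choices and problem sizes

Exact generator identities are asserted to 1e-9 or tighter; estimator
recoveries at zero noise to 1e-6. Medians over even counts are midpoints.
Zero intensities become missing at log2 with a reported count. The
checked claims run at deliberate desk scale: occupancy recovery uses 500
cysteine sites at CV 0.1 (mean absolute error ~1.8-1.9 percentage points
against truth, with an analytic floor of ~1.88 from the
ratio-of-three-replicate-means arithmetic itself), protein-subtraction
nulling uses the study's identification depth as described above,
calibration uses a 10,000-feature null (rejection at alpha = 0.05 lands
near 0.05) and twenty 2,000-feature mixtures for observed FDR (~0.045 at
BH 0.05).

# Worked example

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1)
res <- runAll(cfg, outdir = "demo_run")
head(res$occupancy)
res$manifest
```

# Known limitations

* Occupancy compares +NEM signal to a pooled reference; if protein
  abundance itself shifts across conditions the percentage tracks
  pi x (protein level / pooled mean level), exactly as the ratio
  definition implies -- interpretation of occupancy differences assumes
  approximately stable protein levels, which is why the pipeline also
  reports protein-adjusted site abundances.
* Phosphosite stoichiometry is not estimable from this design (no total
  reference exists for phospho); phospho results are relative abundances.
* The q-value implementation fixes lambda = 0.5 rather than fitting a
  spline over lambda; with few tests (typical set counts) this is the
  stabler choice but can differ from other q-value software.
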