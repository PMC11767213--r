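---
title: "Methods: fingerprint processing, forest inference and enrichment in leafprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint processing, forest inference and enrichment in leafprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafprint)
```

# Overview

`leafprint` analyses flow-infusion electrospray ionisation mass spectrometry
(FIE-MS) metabolite fingerprints of plant leaf tissue. In flow infusion the
extract is infused without chromatographic separation, so each acquisition is
a composite mass spectrum of everything that ionises; the analysis therefore
works on *spectral bins* (fixed-width m/z intervals, one feature per bin per
ionisation mode) rather than resolved chromatographic peaks. The pipeline
covers five stages:

1. **Binning** — centroided scans to a filtered, normalised, log2 feature
   matrix.
2. **Annotation** — accurate-mass molecular formula candidates under
   electrospray adduct rules, with a consensus chemical-taxonomy lineage per
   feature.
3. **Forest inference** — random-forest classification (vote margins,
   permutation significance, proximity ordination) and regression against
   sampling time (out-of-bag R², importance-based feature selection).
4. **Trends** — k-means clustering of log2 abundance-ratio profiles across
   diurnal sampling times.
5. **Enrichment** — structural over-representation (Fisher's exact test,
   Benjamini–Hochberg) and diffusion pathway enrichment (personalized
   PageRank with an empirical random-seed null).

Because the package is validated entirely against synthetic data with known
ground truth, the synthetic-data generator is a first-class module: its
defaults encode the study design the pipeline targets, and every stage's
tests measure recovery of what the generator planted.

# The synthetic-data generator

`synthetic_spec()` describes a design: classes of biological samples (e.g.
two garden locations of one cultivar, or six varieties), four diurnal
sampling times, pooled-QC injections, and a bin set split across positive and
negative ionisation modes. The defaults mirror a realistic field design:
24 samples per class, timepoints 09:00/12:00/18:00/00:00 encoded as hours
0/3/9/15 since first sampling (midnight is the midnight *after* 18:00, since
sampling runs over a single day), 500 bins, 5 pooled QCs.

The intensity model is multiplicative log-normal, the standard working
assumption for MS intensity data. On the log2 scale, sample $i$, bin $j$:

$$y_{ij} = b_j + \delta_j\,[\text{class}(i) = c_j] + a_{k(j)}(t_i) + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma^2)$$

* $b_j \sim U(10, 20)$ — per-bin baseline, i.e. raw intensities spanning
  $2^{10}$–$2^{20}$, a typical Orbitrap dynamic range;
* $\delta_j = \pm$ `effect_size` for the planted discriminating bins, applied
  to one (cycled) class with alternating sign;
* $a_k$ — the planted trend archetype (one log2 offset per timepoint,
  e.g. rise-then-fall `c(0, 1, 2, 1)`);
* $\sigma$ = `noise_sd`, default 0.3 log2 units (~23% CV), a realistic
  biological+technical spread for leaf fingerprints.

Raw intensities are $2^{y}$. Pooled-QC rows are drawn multiplicatively around
the per-bin grand mean with relative s.d. `qc_rsd` (default 5%, typical of a
well-behaved instrument). Detection-limit dropout sets raw values in the
lowest-intensity *quartile* to zero with probability `zero_rate` — dropout in
MS is intensity-dependent, not missing-at-random, and modelling it this way
is what makes the occupancy filter's behaviour testable.

What the generator deliberately does **not** emulate: isotope envelopes,
in-source fragmentation, adduct correlation between bins of the same
compound, chromatographic or batch drift, and heteroscedastic noise at the
low-intensity end. Tests passing on this generator therefore demonstrate the
*algorithms* are correct and calibrated, not that any particular real-world
dataset will satisfy the model.

`matrix_to_scans()` inverts binning for round-trip validation: each sample
row becomes a set of centroided scans whose per-scan intensities follow a
triangular infusion profile, with optional ppm-scale centroid jitter. Two
profile normalisations are offered because they serve different checks:
`scale = "window"` (default) scales the profile so its mean over the
automatically selected scan window is 1, making *binning after expansion the
exact identity*; `scale = "tic"` makes the profile sum to 1 so the summed
scan TIC equals the sample's total intensity. A single normalisation cannot
satisfy both properties for a non-flat profile, so the choice is explicit.
Jitter greater than half a bin width at the top of the m/z range is refused
outright, since bins would no longer be identifiable.

# Binning and filtering

Scans are read from centroided mzML (via `mzR`); profile-mode spectra and
spectra lacking polarity metadata are rejected with instructive errors. The
infusion scan window is the maximal contiguous run of scans with TIC at or
above 50% of the maximum scan TIC (configurable); this tracks the infusion
plateau without assuming a parametric profile shape.

Binning sums centroid intensities into half-open intervals
$[k\,w, (k+1)\,w)$ with $w = 0.01$ m/z by default, separately per ionisation
mode and per scan, then averages over the scans in the window. Bin ids
encode the mode and the bin's lower edge at bin-width precision (`n341.11`).
Each bin also carries its **intensity-weighted mean centroid m/z** as an
accurate representative mass. This matters downstream: a 0.01-Da bin centre
is up to ~25 ppm from any true ion m/z near m/z 200, so annotation at a
3 ppm tolerance must use the accurate within-bin mass, not the bin label.
When a matrix is loaded from text without that metadata, annotation falls
back to the bin midpoint and will only be meaningful at correspondingly
coarse tolerances.

The post-processing chain is stage-gated
(`raw → occupancy_filtered → qc_filtered → normalised → log2`; a filter may
be re-applied at its own output stage, where it is a no-op):

* **Occupancy filter** — keep a bin iff in at least one class the fraction
  of biological samples with non-zero intensity reaches 2/3. The
  within-best-class rule keeps features present in only one class — exactly
  the features a classifier needs.
* **QC-RSD filter** — keep a bin iff sd/mean over pooled-QC injections is
  ≤ 0.5 (inclusive; n−1 s.d.). Bins with zero QC mean are dropped.
* **TIC normalisation** — scale each sample row to the median
  pre-normalisation row sum. The median target is scale-free and
  deterministic.
* **log2** — zeros are imputed as half the smallest non-zero value in the
  matrix (global half-minimum: simple, monotone, and it preserves the
  ordering of all positive values), then log2.

The thresholds are standard fingerprinting practice rather than values with
a principled derivation; all are exposed in the configuration.

# Annotation

For an observed m/z in mode $m$, every (formula, adduct rule) pair with
theoretical m/z $(n M + s)/z$ within the ppm tolerance becomes a candidate.
The default rule set is [M+H]+, [M+Na]+, [M+K]+, [M+NH4]+, [2M+H]+ in
positive mode and [M−H]−, [M+Cl]−, [M+HCOO]−, [2M−H]− in negative mode, with
electron mass included in all shifts and an applicability predicate per rule
(deprotonation requires at least one hydrogen). The tolerance default is
3 ppm, the nominal mass accuracy of a 120k-resolution Orbitrap acquisition;
it is configurable because the operative cutoff on real data depends on
calibration state. Compounds flagged `source = "primary"` are searched
first; `"fallback"` compounds are consulted only when the primary source
yields nothing — mirroring a KEGG-first / PubChem-second lookup strategy.

The consensus classification walks the taxonomy from the most general level
down. At each level the modal term is computed among compounds still
consistent with the accepted prefix; the level is accepted iff the modal
frequency is ≥ 0.66. A tie for the modal term stops the walk at the previous
level — conservative and deterministic. Consensus is computed over distinct
matched *compounds* (not compound–adduct products), since the taxonomy
describes molecules, not ions. Two provable properties anchor the tests:
tightening the tolerance never adds candidates, and raising the consensus
threshold never deepens a lineage.

# Forest inference

`randomForest` is the forest engine; the statistics around it are defined
here.

* **Margin** — per sample, the out-of-bag vote fraction for the true class
  minus the largest vote fraction for any other class; the statistic is the
  mean over samples, in [−1, 1]. Out-of-bag votes avoid resubstitution
  optimism.
* **Permutation test** — labels (or the numeric response) are permuted; a
  *fresh forest* is fitted per permutation; significance uses the add-one
  rule $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, so $p$ is never
  0 and is exactly uniform under exchangeability. Defaults to $B = 3000$,
  reducible in configuration — the calibration tests use $B = 200$ with
  40-sample, 300-feature null datasets, sizes at which a single CPU can run
  200 replicate calibration datasets in minutes.
* **Proximity** — fraction of trees in which two samples co-occupy a
  terminal node, counted over out-of-bag co-occurrences; $d = 1 - $
  proximity is the dissimilarity (no triangle inequality guaranteed, and
  none assumed).
* **Ordination** — classical (Torgerson) scaling implemented directly
  (double-centring $-D^2/2$, top-2 eigenpairs); negative eigenvalues among
  the requested dimensions are truncated with a warning. Class clouds get a
  95% multivariate-normal ellipse: centre = mean, shape = sample covariance,
  boundary at the $\chi^2_2$ quantile.
* **Pairwise dendrogram** — for every class pair a binary forest's margin is
  recorded; the margin matrix is treated as a dissimilarity (more separable
  = more distant) and clustered by average linkage, ties resolved by the
  deterministic lexicographic class order of the dissimilarity input.
* **Regression** — out-of-bag $R^2 = 1 - \mathrm{MSE}_{oob}/\mathrm{var}(t)$
  (can be negative on noise, which the tests assert). Feature selection
  compares each feature's %IncMSE against its own null distribution from
  response-permutation refits, threshold $p < 0.05$ without multiplicity
  adjustment — the selection is deliberately liberal because the selected
  set feeds exploratory trend clustering, not confirmatory claims.

A practical note on forest size: 1000 trees is the default for single fits;
permutation nulls use the same tree count as their observed fit (anything
else would bias the comparison), and tests scale tree counts down (25–100)
where only calibration, not margin precision, is being measured.

# Trend clustering

For each selected feature, the profile is the per-timepoint median log2
value minus the baseline (09:00) median — a difference of log2 values, i.e.
a log2 abundance ratio. Medians, not means, keep single-sample outliers from
bending a profile. Profiles are clustered with Euclidean k-means, 10 seeded
restarts, best within-cluster sum of squares kept. The default $k = 5$ is a
conventional choice for diurnal shape families; since no principled $k$
exists for these data, `kmeans_elbow()` reports the WCSS curve so users can
justify their own. The degenerate $k = $ #features case (every feature its
own cluster, WCSS 0) is handled explicitly because the Hartigan–Wong
algorithm requires $k < n$.

# Enrichment

Structural enrichment is a one-sided Fisher's exact test per taxonomy term
on the 2×2 table {in cluster vs not} × {annotated vs not}, adjusted by
Benjamini–Hochberg within each cluster (Bonferroni available). The
background set is the set of clustered (classified explanatory) features,
configurable. The test equals the hypergeometric tail exactly, which the
suite verifies against an independent pmf summation on hundreds of random
tables.

Functional enrichment runs personalized PageRank on an undirected
compound–reaction–pathway graph (a deliberate simplification of richer
multi-layer metabolic hierarchies; the layer list is extensible), with
restart mass uniform on the cluster's matched compounds and damping 0.85.
Significance is an empirical p-score: the same scoring is repeated for
`n_null` random compound seed sets of equal size, and
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{null})$ — the add-one
rule again, so a reported 0 is impossible and printed p-scores of "0.000"
should be read as "< 1/(1+n_null)". Note that mass concentrates near the
seeds as damping *decreases* (the restart probability is $1-$ damping); the
test suite pins this monotonicity.

# Numerical choices and degenerate inputs

* Half-open binning uses `floor(mz / w + 1e-6)`: the guard absorbs IEEE
  representation error so that a centroid printed as 100.010 lands in
  [100.01, 100.02), while being far too small to misplace any physically
  distinct centroid.
* Permutation p-values can never be 0 (add-one rule) and are reproducible:
  every stochastic function takes a seed, and the pipeline derives per-stage
  seeds from one master seed by hashing the stage name, so stages can be
  re-run independently yet identically. All derived seeds stay below
  $2^{31}$.
* Single-sample normalisation is the identity (its own row sum is the
  median); all-zero rows are an error naming the sample.
* Classes with fewer than 2 samples are excluded (with a message) from the
  pairwise dendrogram and are an error in the classifier.
* QC filtering with fewer than 2 QC injections is an error — an RSD cannot
  be estimated.
* The margin under exactly tied votes is 0; vote rows are renormalised to
  sum to 1 to guard against rare zero-out-of-bag rounding.

# Problem sizes used in validation

The shipped validation suite runs entirely on synthetic data generated at
test time: the round-trip check uses a 50-sample × 500-bin matrix; permutation
calibration uses 200 replicate null datasets of 40 samples × 300 features
with 200 permutations each (forest size 25 for these calibration-only fits);
power and recovery use 50 replicates with 10 planted bins at effect
3 × `noise_sd`; the end-to-end demo uses 48 samples × 500 bins with 200
permutations. These sizes were chosen so the whole suite completes on a
single CPU in well under half an hour while leaving the Monte-Carlo
tolerances meaningful.

# Known limitations

* Annotation is accurate-mass only: no isotope pattern scoring, no MS/MS,
  and no retention-based evidence; candidates are putative by construction.
  A `confirmed_level` column can be attached by users holding
  standards-based confirmation.
* The knowledge graph is a toy three-layer structure; real metabolic
  networks have enzyme/module layers and directionality the p-score null
  does not model.
* `1 - proximity` is not a metric; MDS on it is a visual summary, not an
  isometry.
* The QC filter assumes pooled QCs bracket the technical variance of all
  bins; drift and batch structure are out of scope (no correction beyond
  filtering is applied).
* With 0.01-Da bins, distinct compounds whose adduct ions fall in one bin
  are inseparable; consensus classification over all matches is the
  designed mitigation, not a resolution.
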