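---
title: "Methods: the fiberMSI spatial metabolomics pipeline"
author: "fiberMSI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fiberMSI spatial metabolomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

fiberMSI turns MALDI mass spectrometry imaging (MSI) of skeletal muscle
into fiber-type-resolved metabolomics: from imzML datacubes through
preprocessing, statistics, spatial segmentation, immunofluorescence
co-registration, annotation and set enrichment, to cross-validation
against LC-MS tables. This vignette is the package's own account of the
models and the choices behind them; every number it mentions is computed
by the test suite or by `scripts/acceptance.R`, not asserted from
memory.

## Data model

An `MSIDataset` holds one spectrum per occupied pixel on a 2-D grid with
0-based `(x, y)` indices (origin top-left, x = column — the raster
convention shared by the mask formats) and physical spacing in µm.
Missing pixels are simply absent and render as `NA` in ion images; they
never enter statistics. The processed datacube is a `PeakTable`, a
`SummarizedExperiment` whose rows are consensus m/z features and whose
columns are pixels — so the full Bioconductor tooling applies to it.

## Preprocessing

**Baseline removal** uses a morphological opening: a rolling minimum
followed by a rolling maximum with a structuring element of
`baseline_window` m/z bins (default 51; even widths are promoted to
odd). The opening passes under peaks narrower than the window and tracks
smooth chemical background, so subtraction preserves peak apexes (an
isolated Gaussian survives within 1% of its height) while flattening
drift. The closed-source tools this mirrors do not document their exact
algorithm; the opening is the standard transparent choice.

**Peak picking** estimates noise robustly as
`1.4826 × median(|I − median(I)|)` and reports local maxima whose
excursion *above the noise floor*, `(I − median(I)) / noise`, reaches
`snr_min` (default 3). The excursion form matters: baseline-corrected
noise is non-negative, so a raw `I/noise` ratio is offset by the noise
median and would pass pure noise through any practical gate. Apex m/z is
refined by parabolic interpolation of the three log-intensities around
the maximum — exact for a sampled Gaussian — which makes apex positions
reproducible across pixels to a small fraction of a bin, a prerequisite
for ppm-level alignment on coarser profile grids.

**Alignment** pools all picked peaks, sorts by m/z, and cuts wherever
the relative gap between consecutive peaks exceeds `align_tol_ppm`
(default 10 ppm, mirroring the annotation tolerance). For sorted 1-D
data this is exactly a single-linkage clustering cut. Consensus m/z is
the intensity-weighted member mean (always inside the member span);
per pixel the apex intensity is stored, 0 if absent, and features seen
in fewer than `min_pixel_fraction` of pixels are dropped (default 0.01;
the phantom configurations use 0.3 because their planted features are
ubiquitous).

**Normalization** divides each pixel column of the aligned table by the
RMS of its picked (nonzero) intensities, so every normalized column has
RMS exactly 1 — an invariant the `PeakTable` validity method enforces.
Normalizing after alignment (rather than normalizing each pixel's peak
list first) keeps the invariant true even when alignment drops features.
Note one side effect relevant to interpretation: per-pixel RMS
normalization couples features within a pixel, so a class whose marker
features are boosted shows mildly *depressed* normalized values on all
other features. Recovery-oriented analyses (fold-change fidelity, ICC
calibration) therefore run unnormalized (`normalize = FALSE`).

**Ion-image denoising** is a NaN-aware median filter (default 3×3):
missing pixels are excluded from windows and stay missing. Medians
preserve step edges between homogeneous fiber regions, remove
single-pixel impulses, and are idempotent on piecewise-constant images.
It is applied to the feature images used for segmentation, never to the
stored table.

## Segmentation

Pixel vectors are optionally median-denoised per feature image, then
z-scored per feature (otherwise high-abundance lipids dominate the
Euclidean metric), and clustered by K-means with k-means++
initialization at a fixed seed, 10 restarts, best inertia kept. A Ward
dendrogram over the class centroids summarizes between-class structure
and guides `mergeClasses()`, which implements the "semi-supervised"
step: operator-driven merging/curation of unsupervised classes against
histology. Merging recomputes centroids as pixel-count-weighted means,
so total mass (count × centroid summed over classes) is conserved. `k`
defaults to the study-scale 9 but is a config parameter; the phantom
analyses use the planted class count.

## Co-registration and composition

Adjacent thin sections justify a rigid-plus-scale model, so landmarks
are fitted with a closed-form least-squares similarity transform
(complex-variable Procrustes; no reflection). Label masks are resampled
by nearest-neighbor lookup through the inverse transform — labels are
categorical, interpolation would invent classes — with out-of-bounds
pixels becoming background. Composition tables cross-tabulate co-occupied
pixels (MSI class × fiber type), normalize rows, and convert fractions
to an ordinal 0–3 "+" score: the number of band thresholds
(default 0.05, 0.25, 0.50) at or below the fraction. The bands are
configurable because the published "+" scale prints no numeric cutoffs.

## Per-feature statistics

The pooled (Student's) two-sample t is the default, as in the source
figure legends, vectorized across features with BH-adjusted p alongside
raw p (screening uses raw `p < 0.05`); Welch is available behind a flag.
AUC is the rank (Mann–Whitney) form with midranks for ties; a feature is
discriminative when AUC ≥ 0.7 *or* ≤ 0.3 — the symmetric reading, since
direction depends on group orientation. Reproducibility uses ICC(C,k):
two-way mixed model, consistency, average measures, computed from ANOVA
mean squares as `(MS_target − MS_error)/MS_target`, with bands ≥ 0.75
excellent, 0.60–0.75 good, 0.40–0.60 fair, < 0.40 poor. The estimator is
slightly biased low for few targets (E[1/MS_target] > 1/E[MS_target]);
with the 50-pixel target draws used here the bias is about 0.01 at a
true 0.8 — inside every stated tolerance, and worth knowing when
comparing to the k·σ²T/(k·σ²T+σ²E) closed form. Because the stated
target/rater layout of a replicate study can be ambiguous, the operation
takes an explicit target × rater matrix, so any layout can be expressed;
`replicateICC()` builds those matrices from replicate peak tables
(targets = sampled pixels, raters = replicate acquisitions, log2
intensities).

## Multivariate models

PCA is column-centered SVD with a deterministic sign convention (largest
|loading| positive per component) and variance ratios relative to total
variance. PLS-DA is NIPALS PLS2 on autoscaled X against centered
dummy-coded membership;
`VIP_j = sqrt(p · Σ_a SSY_a w²_ja / Σ_a SSY_a)` with unit weight
vectors, so `Σ VIP² = p` for every fit — an identity the tests check to
1e-6 and the model class enforces. Biomarker selection keeps features
with VIP ≥ 1 and |first-component loading| ≥ 0.05, both inclusive.
Constant columns are dropped with a warning rather than silently
autoscaled to NaN.

## Annotation and enrichment

Annotation matches feature m/z against a metabolite table at 10 ppm
(relative) with [M+H]⁺/[M+Na]⁺/[M+K]⁺ in positive and [M−H]⁻ in
negative mode (electron mass included); database rows may instead carry
precomputed ion masses. All candidates within tolerance are retained,
ranked by |ppm error| — resolving ambiguity needs MS/MS, which is out of
scope.

QEA tests each metabolite set with the globaltest-style quadratic form
`Q = (y − μ̂)ᵀ X Xᵀ (y − μ̂) / (m · μ̂(1 − μ̂))` on the autoscaled member
submatrix. Significance comes from label permutation with the +1
correction (`p = (1 + #{Q_perm ≥ Q_obs})/(1 + n_perm)`, never zero) at a
fixed seed — one permutation draw shared across sets keeps a run
reproducible — and Bonferroni correction across tested sets. An
asymptotic p option is deliberately absent: the permutation null is the
reference.

## The synthetic phantom: what it emulates, and what it does not

`makePhantom()` lays out elongated vertical bands of slow, fast-2a and
fast-2b classes (mimicking longitudinal fiber sections, which is what
makes spatial median denoising meaningful) plus scattered short bands of
a rare oxidative 2b subclass inside the fast-2b region — the planted
analogue of discovering a mitochondria-rich 2b subtype. Rare bands are
two pixels wide, anchored on column pairs fully inside the parent
region: a fiber spans at least two pixels at fine spacing, and narrower
bands would be erased by the 3×3 median and could never be recovered by
any downstream method. The subclass occupies `rareFrac` (default 5%) of
its parent's pixels, capped band-by-band so the realized fraction stays
near target.

`simulateMSI()` builds intensities on the natural-log scale:
`log I = log μ_f + log(2)·effect·[pixel in marker class] + a_fp + b_fr +
ε_fpr`, with feature base abundances log-normal (median 100 a.u.),
planted marker effects of 2 log2 units (4-fold, a strong fingerprint),
pixel-level deviations `a` (variance `sigma2Target`, default 0.0625 —
about 25% CV of biological pixel-to-pixel variation, shared across
replicates), a small per-replicate shift `b` (sd 0.1, removed by the
consistency ICC), and residual noise `ε` with variance `(1/snr)²`
(default snr 4). This makes the per-feature ICC(C,k) expectation exactly
`k·σ²T/(k·σ²T + σ²E)` — the closed form the acceptance suite recovers at
σ²T = σ²E = 1, k = 4 (0.8). Profile mode adds Gaussian peak shapes
(σ 0.35 Da on a 0.2 Da grid, apex = feature intensity), a smooth
exponential additive baseline and a small additive noise floor, and is
writable as imzML. Multiplicative log-normal noise is the package's
choice because MSI intensities are non-negative and heteroscedastic.

What the phantom does *not* emulate: isotope envelopes, matrix-cluster
peaks, mass-dependent resolution, lock-mass drift, tissue-edge
ionization artifacts, or spatially correlated noise. Passing the
recovery tests therefore shows the pipeline's statistics and geometry
are correct under the stated noise model — not that the headline counts
of any real acquisition will be reproduced. Real instrument data remain
the only test of those.

`simulateLCMS()` plants log2 fold changes on chosen features in
log-normal samples (residual sd log 0.3) and emits a matching metabolite
DB and set library (one marker set plus null sets), so annotation,
enrichment and the cross-platform Venn are exercisable end to end with
a shared id namespace.

## Pipeline, determinism and problem sizes

`runPipeline()` consumes one YAML config with per-stage sections; every
threshold and seed is a config key, validation happens before any
computation, and each stage writes its CSV/JSON artifact plus a manifest
recording package version, thresholds and seeds (no timestamps), so
identical configs give byte-identical tabular outputs. Stage failures
abort with the stage name and leave a `FAILED_<stage>` marker.

The shipped analyses run at desk scale, chosen so the full suite and the
acceptance script complete in minutes while keeping every estimate's
Monte-Carlo error well inside its acceptance band: 40×28-pixel phantoms
(1120 spectra) with 60 features for segmentation and recovery, 200
features × 4 replicates at 50 pixel targets for ICC calibration, 1000
features for t-test null calibration, and 4 × 50 null sets at 499
permutations for QEA calibration (200 sets total — a Binomial(50, 0.05)
count alone has ~19% probability of leaving the ±0.03 band even for a
perfect implementation, so the rate is estimated on 200).

## Known limitations

* K-means inertia does not specifically reward isolating very small
  classes: at unfavourable noise seeds a ~17-pixel rare subclass can be
  absorbed while a large class splits. The dendrogram plus
  `mergeClasses()` is the operator's tool for exactly this situation.
* Single-linkage ppm alignment can chain features drifting in small
  steps; with the apex-refinement accuracy achieved here this is not
  observed, but very dense spectra may need a tighter tolerance.
* The QEA direction label is the group with the higher mean autoscaled
  set abundance — a summary, not a per-metabolite direction.
* imzML support covers the common 32/64-bit float, no-compression
  layout; compressed or integer-encoded files are rejected rather than
  guessed at.
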