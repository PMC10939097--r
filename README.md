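# fiberMSI

Spatial metabolomics of skeletal muscle fiber types by MALDI mass
spectrometry imaging (MSI).

Skeletal muscle is a mosaic of slow oxidative (type 1) and fast
glycolytic (type 2a/2x/2b) myofibers with markedly different metabolic
states — acylcarnitines and TCA-cycle intermediates mark oxidative
fibers, methylhistidine dipeptides such as anserine mark glycolytic
ones. MSI measures a full mass spectrum at every 25–50 µm pixel of a
tissue section and can, in principle, classify these metabolic states
*in situ* and even discover new fiber subtypes (e.g. an oxidative,
mitochondria-rich subclass hidden inside the type 2b population). Doing
that reproducibly requires a chain of processing and statistics that is
usually spread over several closed-source tools. fiberMSI implements
that chain as one tested, scriptable R package, for MSI analysts and
muscle physiologists:

* **imzML I/O** — reads and writes the open imzML/ibd standard
  (continuous and processed dialects).
* **Preprocessing** — morphological (opening) baseline removal, MAD-based
  peak picking with parabolic apex refinement, single-linkage ppm peak
  alignment into a consensus feature × pixel table, per-pixel
  root-mean-square (RMS) normalization, NaN-aware edge-preserving median
  denoising of ion images.
* **Segmentation** — K-means (k-means++ init, 10 restarts) over
  standardized feature images with a Ward dendrogram over class
  centroids and operator-guided class merging; the "semi-supervised"
  segmentation workflow.
* **Co-registration** — least-squares similarity transform from landmark
  pairs, nearest-neighbor mask resampling, and ordinal ("+"-score)
  MSI-class × fiber-type composition tables.
* **Statistics** — per-feature pooled t with BH correction, ROC AUC
  screening (discriminative when AUC ≥ 0.7 or ≤ 0.3), reproducibility by
  intraclass correlation ICC(C,k) (two-way mixed model, consistency,
  average measures; bands 0.75/0.60/0.40), PCA, and NIPALS PLS-DA with
  Variable Importance in Projection (VIP; Σ VIP² = p) and the standard
  biomarker gate VIP ≥ 1 & |loading| ≥ 0.05.
* **Annotation** — precise-mass matching against a metabolite table with
  [M+H]⁺/[M+Na]⁺/[M+K]⁺/[M−H]⁻ adducts at 10 ppm.
* **Enrichment** — quantitative metabolite set enrichment (QEA) with a
  globaltest-style statistic `Q = (y−μ̂)ᵀXXᵀ(y−μ̂)/(m·μ̂(1−μ̂))`,
  permutation p-values and Bonferroni correction.
* **Cross-platform validation** — LC-MS feature-table ingestion, the same
  differential machinery, and identity-level Venn overlap.
* **Synthetic phantoms** — a ground-truthed generator that plants
  fiber-type regions (including a rare oxidative 2b subclass),
  class-specific fingerprint markers, log-normal pixel noise, baseline
  drift and replicate-level variance components, so every stage is
  verifiable against known truth.

## Worked example

Simulate a muscle section with a rare oxidative subclass, process it to
a peak table, segment, and score the classes against the (here: known)
fiber-type map:

```r
library(fiberMSI)

phantom <- makePhantom(40, 28, layout = "muscle", seed = 7)
phantom@classMap
#> ROILabelMap: 28 x 40 grid, 4 classes (slow, fast_2a, fast_2b, fast_2b_oxidative)

sim <- simulateMSI(phantom, nFeatures = 60, nMarkersPerClass = 5,
                   snr = 4, replicates = 4, seed = 7)
pt <- processDataset(sim$datasets[[1]], minPixelFraction = 0.3)
pt
#> class: PeakTable
#> dim: 60 1120
#> assays(1): intensity
#> rownames(60): mz_114.3753 mz_124.0002 ... mz_987.9766

seg <- segment(pt, k = 4, seed = 42, denoise = TRUE)
composition(seg@labels, phantom@classMap)$glyphs
#>   1     2     3     4
#> 1 ""    ""    ""    "+++"
#> 2 ""    "+++" ""    ""
#> 3 ""    ""    "+++" ""
#> 4 "+++" ""    ""    ""
```

Each of the 60 simulated features collapses to one consensus m/z over
the 1120 pixels; the four K-means classes each map one-to-one onto a
planted fiber type (three "+" = that type dominates the class — note
MSI class 1 capturing the rare `fast_2b_oxidative` subclass, the
planted analogue of discovering a mitochondria-rich 2b subtype). Replicate
acquisitions quantify reproducibility per feature:

```r
icc <- replicateICC(lapply(sim$datasets, processDataset,
                           minPixelFraction = 0.3))
summary(icc$icc)
#>   Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.7413  0.8277  0.8461  0.8674  0.9199  0.9764
```

A median ICC(C,4) of 0.85 under the generator's default variance
components puts most features in the "excellent" (≥ 0.75)
reproducibility band. `runPipeline(config)` chains all stages (plus
annotation, QEA enrichment, PLS-DA biomarker selection and the LC-MS
Venn overlap) from a single YAML config and writes deterministic CSV/JSON
artifacts.

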