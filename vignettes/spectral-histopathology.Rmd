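---
title: "Spectral histopathology of FTIR tissue images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral histopathology of FTIR tissue images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spechist` analyses mid-infrared hyperspectral images of formalin-fixed,
paraffin-embedded (FFPE) tissue sections. Each pixel of such an image holds
an absorbance spectrum over the 1000-3800 cm^-1 range; the biomolecular
fingerprint (1000-1800 cm^-1) carries the glycan, nucleic-acid and protein
bands that distinguish histological structures and, within mucus, normal
from cancerous tissue. This vignette describes the model at each stage,
the tunable parameters, the synthetic data generator used for validation,
and the design choices that were genuinely open.

## Digital de-paraffinization (EMSC)

FFPE sections are imaged without chemical dewaxing, so paraffin bands
(CH~2~/CH~3~ deformation near 1350-1500 cm^-1 and stretching at
2800-3000 cm^-1) contaminate every pixel. The modified extended
multiplicative signal correction models each pixel spectrum $s$ as

$$ s \;=\; c\,m \;+\; \sum_j a_j p_j \;+\; \sum_{k=0}^{4} b_k P_k(\nu) \;+\; \varepsilon $$

where $m$ is a *common target spectrum* (the mean spectrum of one
designated representative tissue image, used unchanged for all samples of
a cohort), the $p_j$ are the mean spectrum and leading principal-component
loadings of a separately measured pure-paraffin image (the *interference
matrix*), and the $P_k$ are Legendre polynomials up to 4th order on the
axis rescaled to $[-1, 1]$ (an orthogonalized parameterization of the
quartic baseline, chosen for conditioning). The corrected spectrum removes
the fitted interference and baseline and normalizes by the target scale:

$$ s_{\mathrm{corr}} \;=\; \bigl(s - \textstyle\sum_j a_j p_j - \sum_k b_k P_k\bigr) / c . $$

Because the least-squares residual is orthogonal to every design column,
re-fitting a corrected spectrum returns $c = 1$ and $a_j = b_k = 0$: the
correction is idempotent.

Two refinements matter in practice:

* **Target orthogonalization.** A tissue-image mean used as target carries
  paraffin itself. If it is used raw, every corrected spectrum retains the
  target's paraffin content (the correction only *normalizes* paraffin to
  the target's level). The model therefore stores as its effective target
  the supplied spectrum projected orthogonal to the paraffin columns —
  and only the paraffin columns: projecting out the baseline columns as
  well would delete genuine broad tissue structure. The model span, and
  hence the fit, is unchanged; the corrected output becomes paraffin-free.
* **Interference variance floor.** Principal components of the paraffin
  image beyond its true variation rank are noise directions; as design
  columns they absorb tissue signal instead of paraffin variability.
  `build_paraffin_basis()` therefore keeps at most `q` components
  (default 9) *and* drops components explaining less than 1% of the
  paraffin variance (`var_floor`). The mean paraffin spectrum can also be
  linearly dependent on the retained loadings (pure scale variation);
  dependent interference columns are dropped at model build, preserving
  the span.

**Paraffin-pixel elimination.** The embedding background consists of
pixels that the model fits almost entirely with interference columns. A
pixel is eliminated when its *paraffin fraction*
$\|\sum_j a_j p_j\| / (\|c\,m\| + \|\sum_j a_j p_j\|)$ exceeds 0.75, or
when $|c| < 0.1$ (a divide-by-near-zero guard; a pixel with essentially no
target-like signal cannot be normalized). Both thresholds are exposed in
`preprocess_params()`; the defaults were set so that pure paraffin is
always flagged and noiseless tissue never is, which the test suite
verifies on synthetic scenes. Eliminated pixels are removed from the
validity mask and rendered white in cluster maps.

**Order of operations.** Each image is Savitzky-Golay smoothed (3rd-order
polynomial, 11-point window — reproducing cubics exactly, with edge
windows handled by the same local polynomial fits), then EMSC is fit on
the *full* 1000-3800 cm^-1 axis (paraffin's strongest bands lie above the
fingerprint and sharpen the elimination), then flagged pixels are dropped
and the image is cropped to the 1000-1800 cm^-1 fingerprint for all
downstream statistics. Smoothing precedes the fit because it stabilizes
the per-pixel least squares; the whole chain is deterministic.

**Known limitation.** The per-pixel free quartic baseline necessarily
absorbs whatever part of the tissue-versus-target deviation is smooth on
the scale of the whole axis. On heterogeneous scenes this means corrected
spectra of a class that differs broadly from the target are slightly
distorted toward the target's smooth shape. This is intrinsic to EMSC
with a free polynomial baseline, does not affect class separability in
our experiments, and is why coefficient-recovery guarantees are stated
for mixtures inside the model span.

## Segmentation

Preprocessed fingerprint spectra of each image are clustered with k-means
(Euclidean distance, best of 10 seeded restarts, at most 300 iterations;
`stats::kmeans` Hartigan-Wong with a deterministic Lloyd fallback for
degenerate inputs). The number of clusters is a user decision after a
sweep (`kmeans_sweep()`, typically k = 3-11, reporting inertia, maps and
centroid spectra); on synthetic scenes with three tissue classes the
correct choice is k = 3 because the paraffin background has already been
eliminated. Cluster heterogeneity is visualized with a Ward dendrogram
over the k centroid spectra (`ward.D2`, consistent with the variance
objective of k-means; k - 1 merges). On real data, clusters are assigned
to histology by comparison with a stained reference section; on synthetic
scenes `assign_clusters()` substitutes majority overlap with the ground
truth, and segmentation quality is scored with the adjusted Rand index.

## Classification

Samples are classified from the spectra of one histology class (mucus or
epithelium) under leave-one-sample-out cross-validation:

1. pool the training samples' pixel spectra and fit a PCA (up to 40
   components, deterministic sign convention: the largest-magnitude
   loading element is positive);
2. select components by a one-way two-group ANOVA on the per-pixel scores
   labeled with their sample's pathology, keeping components with
   p < 0.01 in decreasing explained-variance order, at most 25, without
   multiple-testing correction (a plain 99% per-component significance
   level). If nothing passes — possible under label permutations — the
   single best component is used, so the null pipeline stays defined;
3. fit Fisher's two-class linear discriminant on the selected scores
   (closed form, pooled within-class covariance; a ridge of
   $10^{-6}\,\mathrm{tr}(S_W)/d$ is added when the covariance is near
   singular), oriented so cancer projects above normal, with the
   equal-prior threshold at the midpoint of the projected class means;
4. project the held-out sample's pixels through the fold's PCA and
   discriminant, aggregate pixel scores to a sample score (mean by
   default; median and vote are available), and classify against the
   fold's threshold.

Out-of-fold sample scores (recentred by each fold's threshold) feed the
ROC by threshold sweep; the trapezoid AUC then equals the Mann-Whitney
statistic $U/(n_1 n_0)$, ties counting one half. Sensitivity and
specificity are reported with cancer as the positive class together with
the per-class recall pair, because published summaries phrase results per
class. Note the deliberate pseudoreplication in step 2: pixels of one
sample are treated as independent replicates, mirroring the target
workflow; sample-level validity comes from the leave-one-*sample*-out
design, not from the per-pixel ANOVA.

A sample-level view, `mean_spectrum_pca()`, computes scores of per-sample
mean spectra for the usual PC1/PC2, PC2/PC3, PC3/PC4 scatter inspection.

## Marker analysis

To relate the discriminant to chemistry, selected PC loadings are
compared with glycan standard spectra (GalNAc, GlcNAc, sialic acid).
`loading_similarity()` reports the windowed Pearson correlation after
resolving the inherent sign ambiguity of loadings (the sign maximizing
|r| is chosen and reported). `detect_peaks()` finds local maxima by
topographic prominence (default threshold 5% of the trace range — robust
to baseline ripple; positions refined by three-point parabolic
interpolation, with plateaus of equal samples treated as one peak), and
`match_peaks()` greedily pairs peaks within 8 cm^-1 — the instrument
resolution, below which peak positions are not meaningful; optimal
assignment was not needed at these peak densities. The sialic-acid
reference centers are 1030, 1070, 1152, 1262, 1530, 1650 and 1726
cm^-1; the 1726 cm^-1 ester band is the discriminating feature absent
from the other standards. The packaged standards are synthetic
Gaussian-band caricatures (`glycan_standards()`), intended for simulated
cohorts and tests; measured standards can be supplied as CSV spectra.

## The synthetic cohort generator

No imaging data are distributed, so every stage is validated against a
generator whose statistical structure matches what the analysis assumes:

* **Scenes.** 64 x 64 pixel tiles (32 x 32 for cohort samples, so a
  26-sample study fits in test budgets) on a 1000-3800 cm^-1 axis with
  4 cm^-1 spacing — two points per 8 cm^-1 resolution element. Regions
  are smoothed random fields thresholded into paraffin background
  (35%) and mucus / epithelium / connective tissue in roughly equal
  thirds (quantile thresholds guarantee minimum region sizes).
* **Spectra.** Each pixel is a nonnegative mixture of Gaussian-band
  endmembers plus a random quartic baseline (amplitude <= 0.05, matching
  the EMSC baseline model) and i.i.d. Gaussian noise (sd 0.005
  absorbance). Paraffin abundance is ~1 in the background and 0.2-0.5
  inside tissue (embedding); tissue endmembers deliberately avoid the
  paraffin band regions so the interference basis stays identifiable.
* **Cohorts.** 10 normal + 16 cancer samples. Mucus pixels carry a
  sialylated-glycan component (mean abundance 0.3, 10% pixel jitter);
  in cancer samples this abundance is multiplied by $1 + \delta$ with
  $\delta = 0.5$ by default. Between-sample variability enters as a
  per-sample amplitude multiplier (sd 0.10; removed by EMSC
  normalization, emulating section thickness) and a per-sample sialic
  multiplier (sd 0.12). The sialic sd is the one generator parameter
  calibrated to a stated target: with it, the default-cohort
  leave-one-sample-out AUC averages about 0.95, the regime reported for
  mucus-based classification, without being trivially separable.
  60-120 mucus pixels are drawn per sample for classification.

Everything is a pure function of its configuration and seed; identical
configs give bit-identical cubes.

**What passing tests do and do not show.** The generator provides exact
mixtures, crisp region boundaries, i.i.d. noise, and a cancer effect
confined to one spectral component. Real FFPE images add scattering
artefacts (resonant Mie), water-vapor lines, mixed-pixel boundaries,
focal-plane drift and biological confounders, none of which are
simulated. Passing this suite shows the pipeline is correct and recovers
a known effect of realistic size under controlled conditions — not that
the effect exists, or is recoverable, in any particular clinical cohort.

## Numerical choices and degenerate inputs

* PCA uses an eigendecomposition of the band-space covariance when
  pixels outnumber bands (the common case) and an SVD otherwise; the
  sign convention makes fold models reproducible across platforms.
* Two-group ANOVA F statistics are computed vectorized across components
  (and equal the squared pooled t statistic; the suite asserts this
  identity against `t.test`), which keeps the 30 000-test null
  simulation inside the test budget.
* Zero-variance components are excluded from selection (their p-value is
  undefined); empty selections fall back to the single best component.
* k-means on noiseless scenes can hit Hartigan-Wong's Quick-TRANSfer
  degeneracy; the implementation falls back to Lloyd under the same seed.
* Ties in ROC scores contribute half, preserving the Mann-Whitney
  equivalence exactly, including on heavily tied score sets.
* ENVI output is float32 BSQ; round trips are exact to float32
  precision. Validity masks travel as 0/255 PNG sidecars because ENVI
  has no standard mask field. Proprietary vendor formats are out of
  scope; convert to ENVI first.

## Problem sizes used by the test suite

Module tests run on 12-32 pixel-wide scenes with 8 cm^-1 spacing; the
end-to-end suite uses the default study conditions (26-sample cohorts of
32 x 32 scenes at 4 cm^-1 spacing, five seeds, a 20-permutation null per
seed, and an effect-size sweep over delta in {0, 0.25, 0.5, 1}). These
sizes were chosen so the whole suite completes in well under half an
hour on one CPU while still exercising every stage at full spectral
resolution.
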