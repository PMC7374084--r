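# spechist

Spectral histopathology of mid-infrared hyperspectral tissue images in R.

Formalin-fixed, paraffin-embedded (FFPE) tissue sections can be imaged by
FTIR microspectroscopy without staining: every pixel holds an absorbance
spectrum over 1000-3800 cm⁻¹ whose fingerprint region (1000-1800 cm⁻¹)
encodes the glycan, protein and nucleic-acid composition of the tissue.
`spechist` implements the full analysis chain used to ask whether mucus —
whose mucin glycosylation and sialylation change in colorectal cancer —
separates normal from cancerous samples:

1. **Digital de-paraffinization** by extended multiplicative signal
   correction (EMSC): each pixel spectrum *s* is fit by least squares as

   *s* = *c·m* + Σⱼ *aⱼ pⱼ* + Σₖ *bₖ Pₖ(ν)* + ε,

   with a common target spectrum *m* (mean spectrum of a representative
   tissue image), an interference basis *pⱼ* built from a separately
   measured pure-paraffin image, and a 4th-order polynomial baseline.
   The corrected spectrum (*s* − paraffin − baseline)/*c* is paraffin-free
   and normalized; pixels whose fit is paraffin-dominated are eliminated
   and appear white in cluster maps. Savitzky–Golay smoothing (3rd order,
   11 points) and fingerprint cropping complete the preprocessing.
2. **Segmentation**: seeded best-of-restarts k-means over the corrected
   fingerprint spectra produces color-coded histology-like cluster maps,
   centroid spectra and a Ward dendrogram of cluster heterogeneity.
3. **Classification**: spectra of one histology class (mucus or
   epithelium) feed a PCA; components are selected by per-component
   two-group ANOVA (p < 0.01, at most 25) and classified by Fisher's
   linear discriminant under leave-one-sample-out cross-validation, with
   ROC/AUC, sensitivity and specificity over the out-of-fold sample
   scores.
4. **Marker analysis**: selected PC loadings are compared against glycan
   standard spectra (GalNAc, GlcNAc, sialic acid) by windowed correlation
   and prominence-based peak matching at the 8 cm⁻¹ instrument
   resolution; the 1726 cm⁻¹ ester band is the sialic-acid-specific
   feature.

Because imaging cohorts of this kind are rarely distributable, the package
includes a first-class synthetic generator (`simulate_cohort()` and
friends) producing hyperspectral scenes of mucus/epithelium/connective
tissue in a paraffin background with a tunable cancer effect confined to a
sialylated-glycan component — every stage of the pipeline is tested
against it. See the vignette
(`vignettes/spectral-histopathology.Rmd`) for the models, parameters and
design decisions.

## Worked example

```r
library(spechist)

axis <- default_axis()                       # 1000-3800 cm-1, 4 cm-1 spacing
lib  <- make_component_library(axis, seed = 1)

# one simulated cancer scene plus the pure-paraffin reference
scene    <- simulate_tissue_image(scene_config(seed = 7), lib,
                                  pathology = "cancer", effect_size = 0.5)
paraffin <- simulate_paraffin_image(scene_config(seed = 8), lib)

# EMSC de-paraffinization against a common target spectrum
basis <- build_paraffin_basis(smooth_sg(paraffin), q = 9)
model <- build_emsc_model(target_spectrum(scene$image), basis)
pre   <- preprocess_image(scene$image, model)
pre
#> <preprocessed_image> 4096 pixels fit, 1434 flagged as paraffin
#> <hyper_image> 64 x 64 pixels, 201 bands (1000-1800 cm-1), 2662 valid

# k-means segmentation of the corrected fingerprint image
cm <- kmeans_segment(pre, k = 3, seed = 1)
cm
#> <cluster_map> k = 3, sizes: 887/887/888, inertia = 5.021
segmentation_quality(cm, scene$truth)
#> [1] 1

# full cohort: 10 normal + 16 cancer samples, LOSO classification
cohort  <- simulate_cohort(cohort_config(seed = 1), lib)
records <- extract_class_records(cohort, tissue_class = "mucus")
cv <- loso_cv(records)
cv
#> <loso_result> 26 samples, AUC = 0.925, sensitivity = 0.812, specificity = 0.900
cv$recall_by_class
#> cancer normal
#> 0.8125 0.9000
```

Reading the output: all 1434 embedding-background pixels of the scene were
flagged as paraffin-dominated and eliminated; the three tissue clusters
recover the simulated histology exactly (adjusted Rand index 1); and on a
default simulated cohort the cross-validated mucus classifier reaches an
AUC of 0.925, with 13/16 cancer and 9/10 normal samples correctly
labeled — the regime reported for mucus-based FTIR classification.

Real ENVI cubes are read with `read_envi_cube()` (float32 BSQ/BIL/BIP
with a `wavelength` header field; validity masks as PNG sidecars), and
spectra tables with `read_spectra_table()`. A config-driven pipeline
(`run_pipeline()`, or the `inst/scripts/spechist.R` wrapper with
subcommands `simulate | preprocess | segment | classify | markers |
report`) orchestrates the stages on disk with YAML configuration and full
seed control.

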