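# Cohort-level orchestration: from simulated (or loaded) scenes to
# classification-ready sample records via the full preprocessing and
# segmentation chain.

#' Extract per-sample class spectra from a cohort
#'
#' Runs the full chain for every sample of a cohort: Savitzky-Golay
#' smoothing, EMSC de-paraffinization against the common target spectrum
#' (mean spectrum of the first sample's image by default), elimination of
#' paraffin-dominated pixels, fingerprint cropping, k-means segmentation,
#' assignment of clusters to histology by majority ground-truth overlap
#' (the synthetic stand-in for reference-image assignment), and extraction
#' of the requested tissue class's spectra. A seeded subsample of
#' `pixel_range` pixels per sample is retained.
#'
#' @param cohort an [simulate_cohort()] `ir_cohort`.
#' @param tissue_class `"mucus"` or `"epithelium"`.
#' @param params a [preprocess_params()].
#' @param k clusters for segmentation (default 3: the three tissue
#'   classes; paraffin background is eliminated before clustering).
#' @param n_restarts k-means restarts.
#' @param target optional common target spectrum; default is the mean
#'   spectrum of the first sample (the designated representative image).
#' @param via `"segmentation"` (default: cluster maps + overlap
#'   assignment) or `"truth"` (ground-truth pixel labels directly).
#' @return list of [sample_record()] objects (samples without any pixel
#'   of the class are dropped, mirroring cohorts where not every section
#'   shows every histology).
#' @export
extract_class_records <- function(cohort, tissue_class = c("mucus", "epithelium"),
                                  params = preprocess_params(), k = 3L,
                                  n_restarts = 10L, target = NULL,
                                  via = c("segmentation", "truth")) {
  tissue_class <- match.arg(tissue_class)
  via <- match.arg(via)
  stopifnot(inherits(cohort, "ir_cohort"))
  paraffin <- smooth_sg(cohort$paraffin_image, params$sg_window, params$sg_order)
  basis <- build_paraffin_basis(paraffin, q = params$q)
  if (is.null(target))
    target <- target_spectrum(cohort$samples[[1L]]$image, params)
  model <- build_emsc_model(target, basis, params$baseline_order)
  pixr <- cohort$config$pixel_range
  records <- list()
  for (s in cohort$samples) {
    pre <- preprocess_image(s$image, model, params)
    px <- as_spectra_matrix(pre$image)
    if (via == "segmentation") {
      cm <- kmeans_segment(pre, k, seed = s$seed, n_restarts = n_restarts)
      assign <- assign_clusters(cm, s$truth)
      ids <- which(assign == tissue_class)
      if (!length(ids)) { # fall back to the closest cluster by overlap
        keep <- !is.na(cm$labels)
        tab <- table(cluster = cm$labels[keep],
                     histology = s$truth$labels[keep])
        if (!tissue_class %in% colnames(tab)) next
        frac <- tab[, tissue_class] / rowSums(tab)
        ids <- as.integer(names(which.max(frac)))
      }
      ext <- extract_cluster_spectra(pre, cm, ids)
      spectra <- ext$spectra
    } else {
      lab <- s$truth$labels[cbind(px$coords$row, px$coords$col)]
      spectra <- px$spectra[lab == tissue_class, , drop = FALSE]
    }
    if (!nrow(spectra)) next
    n_keep <- withr::with_seed(s$seed + 1L, {
      nk <- if (pixr[1L] == pixr[2L]) pixr[1L] else
        sample(seq(pixr[1L], pixr[2L]), 1L)
      nk <- min(nk, nrow(spectra))
      sort(sample.int(nrow(spectra), nk))
    })
    records[[length(records) + 1L]] <-
      sample_record(s$sample_id, s$pathology, tissue_class,
                    spectra[n_keep, , drop = FALSE],
                    pre$image$wavenumber)
  }
  records
}
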