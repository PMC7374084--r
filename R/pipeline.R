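# Config-driven pipeline commands: simulate | preprocess | segment |
# classify | markers | report. Every command is a plain function of a
# validated config list; all randomness flows from config seeds, so a
# config fully determines all numeric outputs. A thin command-line
# wrapper lives in inst/scripts/spechist.R.

#' Default run configuration
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @return nested config list (see the pipeline vignette for fields).
#' @export
default_run_config <- function(outdir = "spechist_run", seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    cohort = list(n_normal = 10L, n_cancer = 16L, effect_size = 0.5,
                  pixel_range = c(60L, 120L)),
    scene = list(width = 32L, height = 32L, axis_step = 4,
                 noise_sd = 0.005, baseline_amplitude = 0.05),
    preprocess = list(sg_window = 11L, sg_order = 3L, baseline_order = 4L,
                      q = 9L, paraffin_fraction_threshold = 0.75,
                      c_min = 0.1, target_sample = 1L),
    segmentation = list(k = 3L, n_restarts = 10L),
    classification = list(tissue_class = "mucus", n_pcs_max = 40L,
                          alpha = 0.01, cap = 25L, aggregate = "mean"),
    markers = list(tolerance = 8, min_prominence = 0.05)
  )
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys raise a validation error naming them; missing keys take
#' the defaults of [default_run_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param outdir,seed overrides applied after loading.
#' @return validated config list.
#' @export
load_run_config <- function(path = NULL, outdir = NULL, seed = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        badk <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(badk))
          stop("unknown config keys: ",
               paste(paste0(k, "$", badk), collapse = ", "), call. = FALSE)
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else cfg[[k]] <- user[[k]]
    }
  }
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

config_objects <- function(config) {
  axis <- default_axis(config$scene$axis_step)
  scene <- scene_config(width = config$scene$width,
                        height = config$scene$height, axis = axis,
                        noise_sd = config$scene$noise_sd,
                        baseline_amplitude = config$scene$baseline_amplitude)
  ccfg <- cohort_config(n_normal = config$cohort$n_normal,
                        n_cancer = config$cohort$n_cancer,
                        effect_size = config$cohort$effect_size,
                        scene = scene,
                        pixel_range = config$cohort$pixel_range,
                        seed = config$seed)
  params <- preprocess_params(
    sg_window = config$preprocess$sg_window,
    sg_order = config$preprocess$sg_order,
    baseline_order = config$preprocess$baseline_order,
    q = config$preprocess$q,
    paraffin_fraction_threshold = config$preprocess$paraffin_fraction_threshold,
    c_min = config$preprocess$c_min)
  list(axis = axis, scene = scene, cohort = ccfg, params = params,
       lib = make_component_library(axis, seed = config$seed))
}

need_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing artifact '", path, "'; run ", producer, " first",
         call. = FALSE)
  path
}

pipe_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Writes per-sample ENVI cubes, ground-truth label CSVs, the paraffin
#' cube and a sample manifest under `<outdir>/cohort/`.
#'
#' @param config a [load_run_config()] list.
#' @return the manifest path, invisibly.
#' @export
cmd_simulate <- function(config) {
  ob <- config_objects(config)
  dir.create(file.path(config$outdir, "cohort"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- simulate_cohort(ob$cohort, ob$lib)
  man <- data.frame(sample_id = character(), pathology = character(),
                    cube = character(), truth = character(), seed = integer())
  for (s in cohort$samples) {
    base <- file.path(config$outdir, "cohort", s$sample_id)
    write_envi_cube(s$image, base)
    data.table::fwrite(data.table::as.data.table(s$truth$labels),
                       paste0(base, "_truth.csv"), col.names = FALSE)
    man <- rbind(man, data.frame(sample_id = s$sample_id,
                                 pathology = s$pathology,
                                 cube = paste0(s$sample_id, ".hdr"),
                                 truth = paste0(s$sample_id, "_truth.csv"),
                                 seed = s$seed))
  }
  write_envi_cube(cohort$paraffin_image,
                  file.path(config$outdir, "cohort", "paraffin"))
  data.table::fwrite(man, file.path(config$outdir, "cohort", "manifest.csv"))
  invisible(file.path(config$outdir, "cohort", "manifest.csv"))
}

read_cohort_dir <- function(config) {
  man <- need_artifact(file.path(config$outdir, "cohort", "manifest.csv"),
                       "cmd_simulate")
  man <- data.table::fread(man, data.table = FALSE)
  samples <- lapply(seq_len(nrow(man)), function(i) {
    base <- file.path(config$outdir, "cohort", man$sample_id[i])
    labels <- as.matrix(data.table::fread(paste0(base, "_truth.csv"),
                                          header = FALSE))
    dimnames(labels) <- NULL
    list(sample_id = man$sample_id[i], pathology = man$pathology[i],
         image = read_envi_cube(base),
         truth = structure(list(labels = labels,
                                pathology = man$pathology[i]),
                           class = "ground_truth"),
         seed = man$seed[i])
  })
  list(samples = samples,
       paraffin = read_envi_cube(file.path(config$outdir, "cohort", "paraffin")))
}

#' Preprocess a simulated cohort on disk
#'
#' EMSC de-paraffinization of every cube against the common target
#' (the configured representative sample); writes corrected fingerprint
#' cubes, per-pixel fit tables and flag masks under
#' `<outdir>/preprocessed/`.
#'
#' @param config a [load_run_config()] list.
#' @return output directory, invisibly.
#' @export
cmd_preprocess <- function(config) {
  ob <- config_objects(config)
  co <- read_cohort_dir(config)
  out <- file.path(config$outdir, "preprocessed")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paraffin <- smooth_sg(co$paraffin, ob$params$sg_window, ob$params$sg_order)
  basis <- build_paraffin_basis(paraffin, q = ob$params$q)
  target <- target_spectrum(
    co$samples[[config$preprocess$target_sample]]$image, ob$params)
  model <- build_emsc_model(target, basis, ob$params$baseline_order)
  for (s in co$samples) {
    pre <- preprocess_image(s$image, model, ob$params)
    base <- file.path(out, s$sample_id)
    write_envi_cube(pre$image, base)
    data.table::fwrite(pre$fits, paste0(base, "_fits.csv"))
  }
  invisible(out)
}

#' Segment preprocessed cubes
#'
#' k-means cluster maps (white = eliminated pixels), centroid CSVs,
#' newick dendrograms and a JSON report under `<outdir>/segmentation/`.
#'
#' @param config a [load_run_config()] list.
#' @return the report path, invisibly.
#' @export
cmd_segment <- function(config) {
  co <- read_cohort_dir(config)
  pin <- file.path(config$outdir, "preprocessed")
  out <- file.path(config$outdir, "segmentation")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rep <- list()
  for (s in co$samples) {
    pre <- read_envi_cube(need_artifact(
      file.path(pin, paste0(s$sample_id, ".hdr")), "cmd_preprocess"))
    cm <- kmeans_segment(pre, config$segmentation$k, seed = s$seed,
                         n_restarts = config$segmentation$n_restarts)
    base <- file.path(out, s$sample_id)
    render_cluster_map(cm, paste0(base, "_clusters.png"))
    data.table::fwrite(data.table::as.data.table(cm$centroids),
                       paste0(base, "_centroids.csv"))
    write_dendrogram_newick(centroid_dendrogram(cm),
                            paste0(base, "_dendrogram.nwk"))
    labs <- data.table::as.data.table(cm$labels)
    data.table::fwrite(labs, paste0(base, "_labels.csv"), col.names = FALSE)
    ari <- segmentation_quality(cm, s$truth)
    rep[[s$sample_id]] <- list(k = cm$k, inertia = cm$inertia,
                               sizes = cm$sizes, ari_vs_truth = ari)
  }
  pipe_json(rep, file.path(out, "segmentation_report.json"))
  invisible(file.path(out, "segmentation_report.json"))
}

#' Classify a preprocessed, segmented cohort
#'
#' Rebuilds sample records from the corrected cubes and cluster labels
#' (clusters assigned to histology by ground-truth overlap), runs the
#' leave-one-sample-out PCA/ANOVA/LDA analysis, and writes the JSON
#' report and ROC CSV under `<outdir>/classification/`.
#'
#' @param config a [load_run_config()] list.
#' @return the report path, invisibly.
#' @export
cmd_classify <- function(config) {
  co <- read_cohort_dir(config)
  pin <- file.path(config$outdir, "preprocessed")
  sin <- file.path(config$outdir, "segmentation")
  out <- file.path(config$outdir, "classification")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cls <- config$classification$tissue_class
  records <- list()
  for (s in co$samples) {
    pre <- read_envi_cube(need_artifact(
      file.path(pin, paste0(s$sample_id, ".hdr")), "cmd_preprocess"))
    labs <- as.matrix(data.table::fread(need_artifact(
      file.path(sin, paste0(s$sample_id, "_labels.csv")), "cmd_segment"),
      header = FALSE))
    dimnames(labs) <- NULL
    px <- as_spectra_matrix(pre)
    clab <- labs[cbind(px$coords$row, px$coords$col)]
    keep <- !is.na(clab)
    tab <- table(cluster = clab[keep],
                 histology = s$truth$labels[pre$valid_mask][keep])
    assign <- colnames(tab)[apply(tab, 1L, which.max)]
    ids <- as.integer(rownames(tab)[assign == cls])
    sel <- which(clab %in% ids)
    if (!length(sel)) next
    pixr <- config$cohort$pixel_range
    rows <- withr::with_seed(s$seed + 1L, {
      nk <- min(if (pixr[1L] == pixr[2L]) pixr[1L] else
        sample(seq(pixr[1L], pixr[2L]), 1L), length(sel))
      sort(sample(sel, nk))
    })
    records[[length(records) + 1L]] <-
      sample_record(s$sample_id, s$pathology, cls,
                    px$spectra[rows, , drop = FALSE], pre$wavenumber)
  }
  cv <- loso_cv(records,
                n_pcs_max = config$classification$n_pcs_max,
                alpha = config$classification$alpha,
                cap = config$classification$cap,
                aggregate = config$classification$aggregate)
  data.table::fwrite(cv$roc, file.path(out, "roc.csv"))
  pipe_json(list(n_samples = nrow(cv$per_sample),
                 tissue_class = cls,
                 auc = cv$auc, sensitivity = cv$sensitivity,
                 specificity = cv$specificity,
                 recall_by_class = as.list(cv$recall_by_class),
                 confusion = as.list(cv$confusion),
                 per_sample = cv$per_sample,
                 selected_pcs = lapply(cv$folds,
                                       function(f) f$selection$selected)),
            file.path(out, "classification_report.json"))
  invisible(file.path(out, "classification_report.json"))
}

#' Marker analysis of the pooled-spectra PCA
#'
#' Pools the classification records, fits the pooled PCA and ANOVA
#' selection once on the full cohort, and compares selected loadings to
#' the glycan standards; writes `<outdir>/markers/marker_report.json`.
#'
#' @param config a [load_run_config()] list.
#' @return the report path, invisibly.
#' @export
cmd_markers <- function(config) {
  need_artifact(file.path(config$outdir, "classification",
                          "classification_report.json"), "cmd_classify")
  co <- read_cohort_dir(config)
  pin <- file.path(config$outdir, "preprocessed")
  cls <- config$classification$tissue_class
  spectra <- list(); labels <- character()
  for (s in co$samples) {
    pre <- read_envi_cube(file.path(pin, paste0(s$sample_id, ".hdr")))
    px <- as_spectra_matrix(pre)
    tl <- s$truth$labels[pre$valid_mask]
    sel <- tl == cls
    if (!any(sel)) next
    spectra[[length(spectra) + 1L]] <- px$spectra[sel, , drop = FALSE]
    labels <- c(labels, rep(s$pathology, sum(sel)))
    wn <- pre$wavenumber
  }
  X <- do.call(rbind, spectra)
  pm <- suppressWarnings(pca_fit(X, config$classification$n_pcs_max))
  sel <- anova_select(pm$scores, labels,
                      alpha = config$classification$alpha,
                      cap = config$classification$cap)
  rep <- marker_report(pm, sel, wn,
                       tolerance = config$markers$tolerance,
                       min_prominence = config$markers$min_prominence)
  out <- file.path(config$outdir, "markers")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pipe_json(rep, file.path(out, "marker_report.json"))
  invisible(file.path(out, "marker_report.json"))
}

#' Stitch stage reports into one markdown summary
#'
#' @param config a [load_run_config()] list.
#' @return the summary path, invisibly.
#' @export
cmd_report <- function(config) {
  seg <- need_artifact(file.path(config$outdir, "segmentation",
                                 "segmentation_report.json"), "cmd_segment")
  cls <- need_artifact(file.path(config$outdir, "classification",
                                 "classification_report.json"), "cmd_classify")
  mk <- need_artifact(file.path(config$outdir, "markers",
                                "marker_report.json"), "cmd_markers")
  segr <- jsonlite::read_json(seg)
  clsr <- jsonlite::read_json(cls)
  mkr <- jsonlite::read_json(mk)
  lines <- c(
    "# spechist run summary", "",
    sprintf("- samples segmented: %d (mean ARI vs truth: %.3f)",
            length(segr),
            mean(vapply(segr, function(s) s$ari_vs_truth, 0))),
    sprintf("- classification (%s): AUC %.3f, sensitivity %.3f, specificity %.3f",
            clsr$tissue_class, clsr$auc, clsr$sensitivity, clsr$specificity),
    sprintf("- marker rows: %d (best correlation %.3f)",
            length(mkr),
            max(vapply(mkr, function(r) r$correlation, 0))), "")
  path <- file.path(config$outdir, "summary.md")
  writeLines(lines, path)
  invisible(path)
}

#' Run the full pipeline end to end
#'
#' simulate -> preprocess -> segment -> classify -> markers -> report.
#'
#' @param config a [load_run_config()] list.
#' @return the summary path, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  cmd_simulate(config)
  cmd_preprocess(config)
  cmd_segment(config)
  cmd_classify(config)
  cmd_markers(config)
  cmd_report(config)
}
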