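# Shared fixtures. Everything is generated in code; heavier cohort-level
# objects are cached per test run so several test files can reuse them.

.fx <- new.env(parent = emptyenv())

# coarse full-range axis (8 cm-1 spacing) for fast module tests
coarse_axis <- function() default_axis(8)

fx_lib <- function(axis = default_axis(), seed = 1L) {
  key <- paste0("lib_", length(axis), "_", seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- make_component_library(axis, seed)
  .fx[[key]]
}

# a small preprocessed scene + its model, for preprocess/segmentation tests
fx_scene <- function(noise_sd = 0.005, seed = 3L, width = 32L, height = 32L,
                     axis = default_axis(), pathology = "cancer",
                     effect_size = 0.5, ...) {
  lib <- fx_lib(axis)
  cfg <- scene_config(width = width, height = height, axis = axis,
                      seed = seed, noise_sd = noise_sd, ...)
  sim <- simulate_tissue_image(cfg, lib, pathology, effect_size)
  par_img <- simulate_paraffin_image(cfg, lib)
  basis <- build_paraffin_basis(smooth_sg(par_img), q = 9L)
  model <- build_emsc_model(target_spectrum(sim$image), basis)
  list(sim = sim, cfg = cfg, lib = lib, model = model, basis = basis)
}

# default-condition cohort records (cached): the study conditions used by
# the end-to-end tests
fx_records <- function(seed, effect_size = 0.5) {
  key <- sprintf("rec_%d_%g", seed, effect_size)
  if (is.null(.fx[[key]])) {
    lib <- fx_lib()
    cc <- cohort_config(effect_size = effect_size, seed = seed)
    .fx[[key]] <- extract_class_records(simulate_cohort(cc, lib))
  }
  .fx[[key]]
}

# simple synthetic sample records in PC-ready form: class means +/- shift
# on a short axis, for classification unit tests
fx_toy_records <- function(n_normal = 5L, n_cancer = 6L, n_px = 30L,
                           shift = 1, noise = 0.05, seed = 1L) {
  axis <- seq(1000, 1100, by = 10)
  base <- sin(seq_along(axis))
  bump <- exp(-0.5 * ((axis - 1050) / 15)^2)
  withr::with_seed(seed, {
    mk <- function(id, pathology) {
      mu <- base + if (pathology == "cancer") shift * bump else 0
      S <- matrix(rep(mu, each = n_px), n_px) +
        matrix(rnorm(n_px * length(axis), sd = noise), n_px)
      sample_record(id, pathology, "mucus", S, axis)
    }
    c(lapply(seq_len(n_normal), function(i) mk(sprintf("N%02d", i), "normal")),
      lapply(seq_len(n_cancer), function(i) mk(sprintf("C%02d", i), "cancer")))
  })
}
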