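# Synthetic hyperspectral tissue scenes and two-group cohorts.
#
# The generator emulates FPA-FTIR tiles of paraffin-embedded colon tissue:
# spatially coherent mucus / epithelium / connective-tissue regions inside a
# paraffin background, every pixel a nonnegative linear mixture of endmember
# spectra plus a smooth quartic baseline and i.i.d. Gaussian noise. The
# cancer effect is an increased abundance of a sialylated-glycan component
# in mucus pixels only.

#' Reference sialic-acid band centers (cm^-1)
#'
#' Characteristic absorption band centers of the sialic-acid glycan
#' standard: 1030, 1070, 1152, 1262, 1530, 1650 and 1726 cm^-1. The
#' 1726 cm^-1 ester band distinguishes sialic acid from the other glycans.
#'
#' @return numeric vector of band centers.
#' @export
sialic_acid_peaks <- function() c(1030, 1070, 1152, 1262, 1530, 1650, 1726)

# fixed band tables (center, sd, amplitude). Tissue endmembers deliberately
# avoid the paraffin CH regions (1350-1500, 2800-3000 cm^-1) so the
# interference basis stays identifiable.
component_bands <- function() {
  b <- function(...) matrix(c(...), ncol = 3L, byrow = TRUE,
                            dimnames = list(NULL, c("center", "sd", "amplitude")))
  list(
    mucus = b(1045, 18, 1.00,  1080, 16, 0.85,  1125, 20, 0.60,
              1550, 18, 0.35,  1655, 20, 0.55,  3300, 80, 0.35),
    epithelium = b(1085, 16, 0.45,  1240, 18, 0.45,  1310, 12, 0.20,
                   1548, 16, 0.75,  1655, 16, 1.00,  3295, 75, 0.50),
    connective = b(1032, 14, 0.55,  1204, 12, 0.50,  1282, 12, 0.50,
                   1338, 10, 0.45,  1552, 16, 0.55,  1660, 20, 0.75,
                   3310, 80, 0.40),
    paraffin = b(1378,  8, 0.45,  1462,  9, 1.00,  1472,  6, 0.60,
                 2848, 14, 1.30,  2916, 16, 1.60,  2954, 10, 0.50),
    sialic_acid_band = b(1030, 12, 0.75,  1070, 12, 0.80,  1152, 13, 0.60,
                         1262, 14, 0.55,  1530, 14, 0.50,  1650, 14, 0.60,
                         1726, 12, 0.90)
  )
}

#' Build the synthetic endmember library
#'
#' Endmembers for mucus, epithelium, connective tissue, paraffin and the
#' sialylated-glycan ("sialic_acid_band") component, each a sum of Gaussian
#' bands on the given axis. The seed drives a small (+/-3%) amplitude
#' jitter so that libraries are reproducible but not all identical.
#'
#' @param axis wavenumber axis; must cover at least 1000-1800 cm^-1.
#' @param seed integer seed.
#' @return object of class `component_library` with fields `wavenumber`,
#'   `endmembers` (named list of [ir_spectrum()]), `matrix` (components x
#'   bands) and `bands` (the band definition tables).
#' @export
make_component_library <- function(axis = default_axis(), seed = 1L) {
  axis <- check_axis(axis)
  if (min(axis) > 1000 || max(axis) < 1800)
    stop("configuration error: axis must cover 1000-1800 cm-1", call. = FALSE)
  if (max(axis) < 1726)
    stop("configuration error: axis must cover the 1726 cm-1 ester band",
         call. = FALSE)
  tabs <- component_bands()
  withr::with_seed(seed, {
    ems <- lapply(tabs, function(tab) {
      amp <- tab[, "amplitude"] * stats::runif(nrow(tab), 0.97, 1.03)
      y <- rep(0, length(axis))
      for (i in seq_len(nrow(tab)))
        y <- y + gaussian_band(axis, tab[i, "center"], tab[i, "sd"], amp[i])
      y
    })
  })
  M <- do.call(rbind, ems)
  rownames(M) <- names(tabs)
  structure(list(wavenumber = axis,
                 endmembers = lapply(ems, ir_spectrum, wavenumber = axis),
                 matrix = M, bands = tabs, seed = seed),
            class = "component_library")
}

#' Scene configuration
#'
#' Defaults are the package's standard simulated study conditions: 64 x 64
#' pixel tiles on the 1000-3800 cm^-1 axis at 4 cm^-1 spacing, additive
#' Gaussian noise of sd 0.005 absorbance, random quartic baselines of
#' amplitude at most 0.05, paraffin abundance 0.2-0.5 within tissue and
#' ~1 in the embedding background.
#'
#' @param width,height scene size in pixels (>= 8).
#' @param axis wavenumber axis.
#' @param seed integer seed; the scene is a pure function of the config.
#' @param noise_sd per-channel Gaussian noise sd (absorbance units).
#' @param baseline_amplitude maximum absolute quartic baseline amplitude.
#' @param paraffin_range paraffin abundance range within tissue pixels.
#' @param background_fraction fraction of the scene that is pure-paraffin
#'   background.
#' @param abundance_jitter relative sd of per-pixel tissue abundance.
#' @param sialic_abundance mean sialylated-glycan abundance in mucus.
#' @param sialic_jitter relative per-pixel sd of the sialic abundance.
#' @param blur_sigma smoothing length of the random region layout fields;
#'   default `width / 10`.
#' @param amp_scale,sialic_scale sample-level multipliers (used by
#'   [simulate_cohort()] to inject between-sample variability).
#' @param paraffin_scale_sd,paraffin_shape_sd jitter of the pure-paraffin
#'   reference image ([simulate_paraffin_image()]).
#' @return object of class `scene_config`.
#' @export
scene_config <- function(width = 64L, height = 64L, axis = default_axis(),
                         seed = 1L, noise_sd = 0.005,
                         baseline_amplitude = 0.05,
                         paraffin_range = c(0.2, 0.5),
                         background_fraction = 0.35,
                         abundance_jitter = 0.05,
                         sialic_abundance = 0.3, sialic_jitter = 0.1,
                         blur_sigma = NULL,
                         amp_scale = 1, sialic_scale = 1,
                         paraffin_scale_sd = 0.05, paraffin_shape_sd = 0.02) {
  if (width < 8L || height < 8L)
    stop("scene width and height must be at least 8 pixels", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 axis = check_axis(axis), seed = as.integer(seed),
                 noise_sd = noise_sd, baseline_amplitude = baseline_amplitude,
                 paraffin_range = paraffin_range,
                 background_fraction = background_fraction,
                 abundance_jitter = abundance_jitter,
                 sialic_abundance = sialic_abundance,
                 sialic_jitter = sialic_jitter,
                 blur_sigma = blur_sigma %||% (width / 10),
                 amp_scale = amp_scale, sialic_scale = sialic_scale,
                 paraffin_scale_sd = paraffin_scale_sd,
                 paraffin_shape_sd = paraffin_shape_sd),
            class = "scene_config")
}

#' Simulate one hyperspectral tissue scene
#'
#' Region layout is drawn from smoothed random fields: a background field
#' selects pure-paraffin embedding pixels, a second field splits the tissue
#' into mucus, epithelium and connective regions of roughly equal size
#' (quantile thresholds guarantee minimum region sizes). Each pixel
#' spectrum is `sum(abundance * endmember) + quartic baseline +
#' N(0, noise_sd)`. In cancer scenes the sialylated-glycan abundance of
#' mucus pixels is multiplied by `1 + effect_size`.
#'
#' @param cfg a [scene_config()].
#' @param lib a [make_component_library()] library on the same axis.
#' @param pathology `"normal"` or `"cancer"`.
#' @param effect_size cancer effect multiplier delta (>= 0); applied only
#'   when `pathology = "cancer"`.
#' @return list with `image` (a [hyper_image()]) and `truth` (class
#'   `ground_truth`: per-pixel histology `labels`, per-pixel `abundances`
#'   matrix, `pathology`).
#' @export
simulate_tissue_image <- function(cfg, lib, pathology = c("normal", "cancer"),
                                  effect_size = 0) {
  pathology <- match.arg(pathology)
  stopifnot(inherits(cfg, "scene_config"), inherits(lib, "component_library"))
  if (!isTRUE(all.equal(cfg$axis, lib$wavenumber)))
    stop("scene config and component library axes differ", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  h <- cfg$height; w <- cfg$width; b <- length(cfg$axis)
  npx <- h * w
  comp <- rownames(lib$matrix)
  delta <- if (pathology == "cancer") effect_size else 0
  withr::with_seed(cfg$seed, {
    f1 <- blur2d(matrix(stats::rnorm(npx), h, w), cfg$blur_sigma)
    tissue <- f1 >= stats::quantile(f1, cfg$background_fraction)
    f2 <- blur2d(matrix(stats::rnorm(npx), h, w), cfg$blur_sigma)
    q <- stats::quantile(f2[tissue], c(1, 2) / 3)
    labels <- matrix("paraffin", h, w)
    labels[tissue & f2 < q[1L]] <- "mucus"
    labels[tissue & f2 >= q[1L] & f2 < q[2L]] <- "epithelium"
    labels[tissue & f2 >= q[2L]] <- "connective"
    lab <- as.vector(labels)
    A <- matrix(0, npx, length(comp), dimnames = list(NULL, comp))
    for (cl in c("mucus", "epithelium", "connective")) {
      i <- lab == cl
      A[i, cl] <- cfg$amp_scale *
        (1 + cfg$abundance_jitter * stats::rnorm(sum(i)))
    }
    ti <- lab != "paraffin"
    A[ti, "paraffin"] <- stats::runif(sum(ti), cfg$paraffin_range[1L],
                                      cfg$paraffin_range[2L])
    A[!ti, "paraffin"] <- 1 + cfg$abundance_jitter * stats::rnorm(sum(!ti))
    mu <- lab == "mucus"
    A[mu, "sialic_acid_band"] <- cfg$sialic_abundance * cfg$sialic_scale *
      (1 + cfg$sialic_jitter * stats::rnorm(sum(mu))) * (1 + delta)
    A <- pmax(A, 0)
    S <- A %*% lib$matrix
    if (cfg$baseline_amplitude > 0) {
      P <- legendre_basis(cfg$axis, 4L)
      cf <- matrix(stats::runif(npx * 5L, -1, 1), npx, 5L)
      S <- S + cf %*% t(P) * (cfg$baseline_amplitude / 5)
    }
    if (cfg$noise_sd > 0)
      S <- S + matrix(stats::rnorm(npx * b, sd = cfg$noise_sd), npx, b)
  })
  truth <- structure(list(labels = labels, abundances = A,
                          pathology = pathology, components = comp),
                     class = "ground_truth")
  list(image = hyper_image(array(S, c(h, w, b)), cfg$axis), truth = truth)
}

#' Simulate a pure paraffin reference image
#'
#' The separately measured paraffin cube used to build the EMSC
#' interference basis. Pixels are the paraffin endmember under small
#' random scale and shape jitter plus noise; no tissue components.
#'
#' @param cfg a [scene_config()] (`paraffin_scale_sd`, `paraffin_shape_sd`
#'   and `noise_sd` control the jitter).
#' @param lib a component library on the same axis.
#' @return a [hyper_image()].
#' @export
simulate_paraffin_image <- function(cfg, lib) {
  stopifnot(inherits(cfg, "scene_config"), inherits(lib, "component_library"))
  h <- cfg$height; w <- cfg$width; b <- length(cfg$axis)
  npx <- h * w
  par <- lib$matrix["paraffin", ]
  dpar <- c(diff(par), 0)
  nrm <- sqrt(sum(dpar^2))
  if (nrm > 0) dpar <- dpar * (0.5 * sqrt(sum(par^2)) / nrm)
  withr::with_seed(cfg$seed, {
    sc <- 1 + cfg$paraffin_scale_sd * stats::rnorm(npx)
    sh <- cfg$paraffin_shape_sd * stats::rnorm(npx)
    S <- outer(sc, par) + outer(sh, dpar)
    if (cfg$noise_sd > 0)
      S <- S + matrix(stats::rnorm(npx * b, sd = cfg$noise_sd), npx, b)
  })
  hyper_image(array(S, c(h, w, b)), cfg$axis)
}

#' Cohort configuration
#'
#' The default cohort mirrors the target study design: 10 normal and 16
#' cancer samples, cancer effect size delta = 0.5 on the sialylated-glycan
#' abundance of mucus. Cohort scenes default to 32 x 32 pixels and 60-120
#' mucus pixels are drawn per sample for classification.
#'
#' @param n_normal,n_cancer sample counts (>= 0, total >= 2).
#' @param effect_size delta, multiplier on the cancer-mucus sialic
#'   abundance (>= 0).
#' @param scene a [scene_config()] template for the per-sample scenes.
#' @param pixel_range range of mucus/epithelium pixel counts retained per
#'   sample when extracting classification spectra.
#' @param sample_amp_sd sd of the per-sample overall amplitude multiplier
#'   (removed by EMSC normalization; emulates section-thickness variation).
#' @param sample_sialic_sd sd of the per-sample sialic abundance
#'   multiplier (biological between-sample variability).
#' @param seed cohort seed; per-sample seeds are derived from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_normal = 10L, n_cancer = 16L, effect_size = 0.5,
                          scene = scene_config(width = 32L, height = 32L),
                          pixel_range = c(60L, 120L),
                          sample_amp_sd = 0.10, sample_sialic_sd = 0.12,
                          seed = 1L) {
  if (n_normal < 0L || n_cancer < 0L || n_normal + n_cancer < 2L)
    stop("cohort needs n_normal, n_cancer >= 0 and at least 2 samples total",
         call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  structure(list(n_normal = as.integer(n_normal),
                 n_cancer = as.integer(n_cancer),
                 effect_size = effect_size, scene = scene,
                 pixel_range = as.integer(pixel_range),
                 sample_amp_sd = sample_amp_sd,
                 sample_sialic_sd = sample_sialic_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a two-group cohort of tissue scenes
#'
#' Generates one scene per sample (per-sample seeds derived
#' deterministically from the cohort seed), sample-level amplitude and
#' sialic-abundance random effects, and the shared pure-paraffin
#' reference image.
#'
#' @param cfg a [cohort_config()].
#' @param lib a component library on the scene axis.
#' @return object of class `ir_cohort`: list with `samples` (each with
#'   `sample_id`, `pathology`, `image`, `truth`, `seed`),
#'   `paraffin_image`, and the `config` echo.
#' @export
simulate_cohort <- function(cfg, lib) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(lib, "component_library"))
  n <- cfg$n_normal + cfg$n_cancer
  pathology <- rep(c("normal", "cancer"), c(cfg$n_normal, cfg$n_cancer))
  withr::with_seed(cfg$seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n + 1L)
    amp <- 1 + cfg$sample_amp_sd * stats::rnorm(n)
    sia <- pmax(1 + cfg$sample_sialic_sd * stats::rnorm(n), 0.2)
  })
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- cfg$scene
    sc$seed <- seeds[i]
    sc$amp_scale <- amp[i]
    sc$sialic_scale <- sia[i]
    sim <- simulate_tissue_image(sc, lib, pathology = pathology[i],
                                 effect_size = cfg$effect_size)
    samples[[i]] <- list(sample_id = sprintf("S%02d", i),
                         pathology = pathology[i],
                         image = sim$image, truth = sim$truth,
                         seed = seeds[i])
  }
  pc <- cfg$scene
  pc$seed <- seeds[n + 1L]
  structure(list(samples = samples,
                 paraffin_image = simulate_paraffin_image(pc, lib),
                 config = cfg),
            class = "ir_cohort")
}
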