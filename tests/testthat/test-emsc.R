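# EMSC model construction, coefficient recovery, and paraffin flagging.

make_basis <- function(noise_sd = 0.001, seed = 4, q = 9) {
  lib <- fx_lib(coarse_axis())
  cfg <- scene_config(width = 12, height = 12, axis = coarse_axis(),
                      seed = seed, noise_sd = noise_sd)
  build_paraffin_basis(smooth_sg(simulate_paraffin_image(cfg, lib)), q = q)
}

test_that("paraffin basis: degenerate, two-point and jittered cases", {
  axis <- coarse_axis()
  lib <- fx_lib(axis)
  par <- lib$matrix["paraffin", ]
  # all pixels identical: zero variance, mean equals the common spectrum
  cube <- array(rep(par, each = 9), c(3, 3, length(axis)))
  img <- hyper_image(cube, axis)
  expect_warning(b0 <- build_paraffin_basis(img, q = 2), "rank")
  expect_equal(b0$mean_paraffin, par, ignore_attr = TRUE)
  expect_equal(b0$q, 0L)
  # two distinct spectra, q = 1: loading parallel to their difference
  s1 <- par; s2 <- par * 1.3 + 0.01
  cube2 <- array(c(rbind(s1, s2)), c(2, 1, length(axis)))
  expect_warning(b1 <- build_paraffin_basis(hyper_image(cube2, axis), q = 1),
                 NA)
  d <- s2 - s1
  cosang <- abs(sum(b1$components[, 1] * d)) / sqrt(sum(d^2))
  expect_equal(cosang, 1, tolerance = 1e-10)
  # jittered image: loading 1 matches the dominant direction from an
  # independent full eigendecomposition of the covariance
  b <- make_basis(noise_sd = 0.001)
  cfg <- scene_config(width = 12, height = 12, axis = axis, seed = 4,
                      noise_sd = 0.001)
  S <- as_spectra_matrix(smooth_sg(simulate_paraffin_image(cfg, lib)))$spectra
  eg <- eigen(stats::cov(S), symmetric = TRUE)
  expect_gt(abs(sum(b$components[, 1] * eg$vectors[, 1])), 1 - 1e-8)
  expect_equal(crossprod(b$components), diag(b$q), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the EMSC design has the documented columns and rejects collinearity", {
  b <- make_basis()
  lib <- fx_lib(coarse_axis())
  target <- ir_spectrum(coarse_axis(),
                        colMeans(lib$matrix[c("mucus", "epithelium"), ]) +
                          0.3 * lib$matrix["paraffin", ])
  m0 <- build_emsc_model(target, b, baseline_order = 0)
  expect_equal(ncol(m0$design), 1 + (b$q + 1) + 1)
  m4 <- build_emsc_model(target, b, baseline_order = 4)
  expect_equal(ncol(m4$design), 1 + (b$q + 1) + 5)
  # target proportional to a basis column -> rank-deficiency error naming it
  bad <- ir_spectrum(coarse_axis(), 2 * b$mean_paraffin)
  expect_error(build_emsc_model(bad, b), "collinear")
})

test_that("EMSC recovers exactly representable coefficients and is idempotent", {
  b <- make_basis()
  lib <- fx_lib(coarse_axis())
  m_raw <- colMeans(lib$matrix[c("mucus", "epithelium", "connective"), ]) +
    0.35 * b$mean_paraffin
  model <- build_emsc_model(ir_spectrum(coarse_axis(), m_raw), b)
  m <- model$target # effective (interference-orthogonal) target
  # identity: s = m
  r <- fit_emsc(model, m)
  expect_equal(r$fit$c, 1, tolerance = 1e-10)
  expect_lt(max(abs(c(r$fit$a, r$fit$b))), 1e-10)
  expect_equal(r$corrected$absorbance, m, tolerance = 1e-8)
  # fitting the raw (paraffin-carrying) target still gives unit scale
  expect_equal(fit_emsc(model, m_raw)$fit$c, 1, tolerance = 1e-10)
  # closed-form recovery: s = 2 m + 0.5 p1 + 0.1 constant
  s <- 2 * m + 0.5 * model$design[, "paraffin_pc1"] + 0.1
  r2 <- fit_emsc(model, s)
  expect_equal(r2$fit$c, 2, tolerance = 1e-8)
  expect_equal(unname(r2$fit$a[["paraffin_pc1"]]), 0.5, tolerance = 1e-8)
  expect_equal(unname(r2$fit$b[["poly0"]]), 0.1, tolerance = 1e-8)
  expect_equal(r2$corrected$absorbance, m, tolerance = 1e-8)
  # idempotence: refitting a corrected spectrum gives c = 1, a = 0
  r3 <- fit_emsc(model, r2$corrected)
  expect_equal(r3$fit$c, 1, tolerance = 1e-8)
  expect_lt(max(abs(r3$fit$a)), 1e-8)
  expect_equal(r3$corrected$absorbance, r2$corrected$absorbance,
               tolerance = 1e-8)
})

test_that("paraffin fraction flags correctly and is monotone in abundance", {
  b <- make_basis()
  lib <- fx_lib(coarse_axis())
  m_raw <- colMeans(lib$matrix[c("mucus", "epithelium", "connective"), ]) +
    0.35 * b$mean_paraffin
  model <- build_emsc_model(ir_spectrum(coarse_axis(), m_raw), b)
  m <- model$target
  params <- preprocess_params()
  pure_par <- fit_emsc(model, lib$matrix["paraffin", ])$fit
  pure_tis <- fit_emsc(model, m)$fit
  expect_true(flag_paraffin_pixels(
    list(c = pure_par$c, paraffin_fraction = pure_par$paraffin_fraction),
    params))
  expect_false(flag_paraffin_pixels(
    list(c = pure_tis$c, paraffin_fraction = pure_tis$paraffin_fraction),
    params))
  # mixture sweep: flag decisions equal a brute-force evaluation of the
  # flagging rule from the known mixing coefficients
  p1 <- b$mean_paraffin
  grid <- expand.grid(cc = c(0.05, 0.2, 0.6, 1, 1.5),
                      aa = c(0, 0.2, 0.8, 2, 6))
  S <- as.matrix(grid$cc) %*% rbind(m) + as.matrix(grid$aa) %*% rbind(p1)
  fits <- spechist:::emsc_correct_matrix(model, S)
  got <- flag_paraffin_pixels(list(c = fits$coefficients[, 1],
                                   paraffin_fraction = fits$paraffin_fraction),
                              params)
  # with the effective target orthogonal to the paraffin columns, the
  # fitted coefficients equal the construction exactly
  np <- grid$aa * sqrt(sum(p1^2))
  nt <- grid$cc * sqrt(sum(m^2))
  oracle <- (np / (nt + np)) > params$paraffin_fraction_threshold |
    grid$cc < params$c_min
  expect_equal(got, oracle)
  # monotonicity: fraction non-decreasing in true paraffin abundance
  aa <- seq(0, 4, length.out = 30)
  S2 <- rbind(m)[rep(1, 30), ] + as.matrix(aa) %*% rbind(p1)
  f2 <- spechist:::emsc_correct_matrix(model, S2)$paraffin_fraction
  expect_true(all(diff(f2) >= -1e-12))
})

test_that("corrected spectra keep biomolecular variance and drop paraffin", {
  # single-class recovery regime: mucus pixels against a mucus-derived
  # target; corrected spectra (rescaled by c) match the pure tissue
  # mixture to within the noise level
  axis <- coarse_axis()
  lib <- fx_lib(axis)
  b <- make_basis()
  n <- 200
  noise_sd <- 0.005
  withr::with_seed(11, {
    a <- 1 + 0.05 * rnorm(n)
    s <- 0.3 * (1 + 0.1 * rnorm(n))
    par <- runif(n, 0.2, 0.5)
    tissue <- outer(a, lib$matrix["mucus", ]) +
      outer(s, lib$matrix["sialic_acid_band", ])
    P5 <- spechist:::legendre_basis(axis, 4)
    base <- matrix(runif(n * 5, -1, 1), n) %*% t(P5) * 0.01
    S <- tissue + outer(par, lib$matrix["paraffin", ]) + base +
      matrix(rnorm(n * length(axis), sd = noise_sd), n)
  })
  # the pipeline smooths every input (paraffin image, target, pixels)
  # with the same filter before fitting; do the same here
  S <- smooth_sg(S)
  tissue_sm <- smooth_sg(tissue)
  target <- colMeans(tissue_sm) +
    mean(par) * smooth_sg(rbind(lib$matrix["paraffin", ]))[1, ]
  model <- build_emsc_model(ir_spectrum(axis, target), b)
  fit <- spechist:::emsc_correct_matrix(model, S)
  rescaled <- fit$corrected * fit$coefficients[, 1]
  # closed-form oracle: a paraffin-free correction can retain only the
  # part of the tissue mixture orthogonal to the paraffin columns;
  # compare against that projection residual
  qPP <- qr(model$design[, model$idx$paraffin])
  tissue_perp <- t(apply(tissue_sm, 1, function(v) qr.resid(qPP, v)))
  rmse <- sqrt(rowMeans((rescaled - tissue_perp)^2))
  expect_lt(stats::median(rmse), 3 * noise_sd)
  # paraffin suppression: mean corrected tissue trace is uncorrelated with
  # the (smoothed) paraffin reference over its 1350-1500 cm-1 bands
  win <- axis >= 1350 & axis <= 1500
  r <- stats::cor(colMeans(fit$corrected)[win], b$mean_paraffin[win])
  expect_lt(abs(r), 0.1)
})
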