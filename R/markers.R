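# Relating discriminant PC loadings to glycan standard spectra: peak
# detection with topographic prominence, greedy peak matching within a
# tolerance of the instrument resolution, windowed loading-standard
# correlation (loadings are sign-ambiguous), and class-difference spectra.

#' A glycan standard spectrum
#'
#' @param name standard name (`"GalNAc"`, `"GlcNAc"`, `"sialic_acid"`, or
#'   a user label).
#' @param spectrum an [ir_spectrum()]; intensities must be nonnegative.
#' @return object of class `glycan_standard`.
#' @export
glycan_standard <- function(name, spectrum) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (any(spectrum$absorbance < 0))
    stop("glycan standard intensities must be nonnegative", call. = FALSE)
  structure(list(name = name, spectrum = spectrum), class = "glycan_standard")
}

#' Synthetic glycan standard spectra
#'
#' Gaussian-band caricatures of the three mucin glycan standards:
#' GalNAc, GlcNAc, and sialic acid. The sialic-acid standard carries the
#' seven reference bands ([sialic_acid_peaks()]) including the
#' 1726 cm^-1 ester band that the other two lack. These are synthetic
#' stand-ins for measured KBr-pellet standards, intended for simulated
#' cohorts and for tests.
#'
#' @param axis wavenumber axis.
#' @return named list of [glycan_standard()] objects.
#' @export
glycan_standards <- function(axis = default_axis()) {
  axis <- check_axis(axis)
  mk <- function(name, tab) {
    y <- rep(0, length(axis))
    for (i in seq_len(nrow(tab)))
      y <- y + gaussian_band(axis, tab[i, 1L], tab[i, 2L], tab[i, 3L])
    glycan_standard(name, ir_spectrum(axis, y))
  }
  b <- function(...) matrix(c(...), ncol = 3L, byrow = TRUE)
  list(
    GalNAc = mk("GalNAc", b(1040, 14, 0.80,  1085, 15, 0.65,  1128, 14, 0.55,
                            1315, 15, 0.30,  1548, 15, 0.50,  1640, 16, 0.55)),
    GlcNAc = mk("GlcNAc", b(1035, 14, 0.80,  1078, 14, 0.70,  1118, 15, 0.55,
                            1310, 14, 0.30,  1550, 15, 0.45,  1632, 16, 0.50)),
    sialic_acid = mk("sialic_acid",
                     b(1030, 12, 0.75,  1070, 12, 0.80,  1152, 13, 0.60,
                       1262, 14, 0.55,  1530, 14, 0.50,  1650, 14, 0.60,
                       1726, 12, 0.90))
  )
}

#' Detect peaks by topographic prominence
#'
#' Local maxima whose topographic prominence (height above the highest
#' saddle separating the peak from any higher point) reaches
#' `min_prominence` times the trace range. Positions are refined by
#' three-point parabolic interpolation.
#'
#' @param s an [ir_spectrum()] or numeric vector (then `wavenumber`
#'   must be given).
#' @param min_prominence prominence threshold as a fraction of the trace
#'   range (default 0.05).
#' @param wavenumber axis when `s` is a bare vector.
#' @return object of class `peak_list`: data.frame with `position`
#'   (cm^-1, strictly increasing) and `prominence` (> 0); may be empty.
#' @export
detect_peaks <- function(s, min_prominence = 0.05, wavenumber = NULL) {
  if (inherits(s, "ir_spectrum")) {
    y <- s$absorbance; x <- s$wavenumber
  } else {
    y <- as.numeric(s); x <- wavenumber %||% seq_along(y)
  }
  n <- length(y)
  if (n < 3L) stop("peak detection needs at least 3 points", call. = FALSE)
  out <- data.frame(position = numeric(), prominence = numeric())
  # local maxima with plateau handling: a run of equal values bounded by
  # strictly lower neighbours is one peak at the run centre
  cand <- integer()
  i0 <- 2L
  while (i0 <= n - 1L) {
    j <- i0
    while (j < n && y[j + 1L] == y[i0]) j <- j + 1L
    if (y[i0] > y[i0 - 1L] && j < n && y[i0] > y[j + 1L])
      cand <- c(cand, as.integer(floor((i0 + j) / 2)))
    i0 <- j + 1L
  }
  rng <- diff(range(y))
  if (rng == 0 || !length(cand))
    return(structure(out, class = c("peak_list", "data.frame")))
  for (i in cand) {
    # walk outwards until a strictly higher point; track the lowest saddle
    left_min <- y[i]
    j <- i - 1L
    while (j >= 1L && y[j] <= y[i]) { left_min <- min(left_min, y[j]); j <- j - 1L }
    if (j < 1L) left_min <- min(y[seq_len(i)])
    right_min <- y[i]
    j <- i + 1L
    while (j <= n && y[j] <= y[i]) { right_min <- min(right_min, y[j]); j <- j + 1L }
    if (j > n) right_min <- min(y[i:n])
    base <- if (i == which.max(y)[1L]) min(y) else max(left_min, right_min)
    prom <- y[i] - base
    if (prom >= min_prominence * rng) {
      # parabolic refinement on (x, y) around the sample maximum
      num <- y[i - 1L] - y[i + 1L]
      den <- y[i - 1L] - 2 * y[i] + y[i + 1L]
      delta <- if (den != 0) 0.5 * num / den else 0
      delta <- max(min(delta, 0.5), -0.5)
      pos <- x[i] + delta * (if (delta >= 0) x[i + 1L] - x[i] else x[i] - x[i - 1L])
      out <- rbind(out, data.frame(position = pos, prominence = prom))
    }
  }
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("peak_list", "data.frame"))
}

#' Match two peak lists within a tolerance
#'
#' Greedy nearest matching: candidate pairs within `tolerance` are
#' accepted in order of increasing distance, each peak used at most once.
#' The default tolerance of 8 cm^-1 equals the instrument resolution --
#' peaks cannot be localized better than that.
#'
#' @param query,reference `peak_list` objects or numeric position
#'   vectors.
#' @param tolerance maximum matching distance in cm^-1 (default 8).
#' @return list with `matches` (data.frame `query`, `reference`,
#'   `distance`), `unmatched_query`, `unmatched_reference`.
#' @export
match_peaks <- function(query, reference, tolerance = 8) {
  qp <- if (is.data.frame(query)) query$position else as.numeric(query)
  rp <- if (is.data.frame(reference)) reference$position else as.numeric(reference)
  pairs <- expand.grid(qi = seq_along(qp), ri = seq_along(rp))
  if (nrow(pairs)) {
    pairs$distance <- abs(qp[pairs$qi] - rp[pairs$ri])
    pairs <- pairs[pairs$distance <= tolerance, , drop = FALSE]
    pairs <- pairs[order(pairs$distance), , drop = FALSE]
  }
  used_q <- logical(length(qp)); used_r <- logical(length(rp))
  keep <- integer()
  for (r in seq_len(nrow(pairs))) {
    qi <- pairs$qi[r]; ri <- pairs$ri[r]
    if (!used_q[qi] && !used_r[ri]) {
      used_q[qi] <- TRUE; used_r[ri] <- TRUE
      keep <- c(keep, r)
    }
  }
  m <- pairs[keep, , drop = FALSE]
  m <- m[order(qp[m$qi]), , drop = FALSE]
  list(matches = data.frame(query = qp[m$qi], reference = rp[m$ri],
                            distance = m$distance, row.names = NULL),
       unmatched_query = qp[!used_q], unmatched_reference = rp[!used_r])
}

#' Windowed correlation between a loading and a glycan standard
#'
#' Pearson correlation of the two traces restricted to the window, after
#' resampling the standard onto the loading axis. Because PC loadings are
#' sign-ambiguous, the loading sign is chosen to maximize the absolute
#' correlation and the chosen sign is reported.
#'
#' @param loading an [ir_spectrum()] (or numeric vector with
#'   `wavenumber`).
#' @param standard a [glycan_standard()] or [ir_spectrum()].
#' @param window wavenumber interval (default the fingerprint).
#' @param wavenumber axis when `loading` is a bare vector.
#' @return list with `correlation` (the maximized value, >= 0 unless the
#'   traces are anticorrelated under both signs), `sign` (+1 or -1
#'   applied to the loading), `raw` (correlation at the stored sign).
#' @export
loading_similarity <- function(loading, standard, window = fingerprint_window(),
                               wavenumber = NULL) {
  if (!inherits(loading, "ir_spectrum"))
    loading <- ir_spectrum(wavenumber, loading)
  std <- if (inherits(standard, "glycan_standard")) standard$spectrum else standard
  stopifnot(inherits(std, "ir_spectrum"))
  lw <- crop_fingerprint(loading, window[1L], window[2L])
  std <- resample_spectrum(std, lw$wavenumber)
  if (stats::sd(lw$absorbance) == 0 || stats::sd(std$absorbance) == 0)
    stop("zero variance in the comparison window", call. = FALSE)
  r <- stats::cor(lw$absorbance, std$absorbance)
  list(correlation = abs(r), sign = if (r >= 0) 1 else -1, raw = r)
}

#' Class-difference spectrum with pointwise confidence band
#'
#' `mean(A) - mean(B)` with pointwise 95% Welch t-intervals. When either
#' group has a single spectrum the difference is returned with the band
#' undefined and flagged.
#'
#' @param A,B spectra matrices (rows = spectra) on a common axis.
#' @param wavenumber the shared axis.
#' @param conf confidence level (default 0.95).
#' @return list with `wavenumber`, `difference`, `lower`, `upper`,
#'   `band_defined`.
#' @export
class_difference_spectrum <- function(A, B, wavenumber, conf = 0.95) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!nrow(A) || !nrow(B)) stop("both groups must be non-empty", call. = FALSE)
  stopifnot(ncol(A) == ncol(B), ncol(A) == length(wavenumber))
  d <- colMeans(A) - colMeans(B)
  if (nrow(A) < 2L || nrow(B) < 2L)
    return(list(wavenumber = wavenumber, difference = d,
                lower = rep(NA_real_, length(d)), upper = rep(NA_real_, length(d)),
                band_defined = FALSE))
  va <- apply(A, 2L, stats::var) / nrow(A)
  vb <- apply(B, 2L, stats::var) / nrow(B)
  se <- sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (nrow(A) - 1L) + vb^2 / (nrow(B) - 1L))
  df[!is.finite(df) | df <= 0] <- nrow(A) + nrow(B) - 2L
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  list(wavenumber = wavenumber, difference = d,
       lower = d - tq * se, upper = d + tq * se, band_defined = TRUE)
}

#' Marker report: compare selected PC loadings to glycan standards
#'
#' For each selected component of a pooled-spectra PCA, computes the
#' windowed correlation against each standard and matches detected peaks
#' against the sialic-acid reference centers.
#'
#' @param pm a [pca_fit()] model over pooled class spectra.
#' @param selection an [anova_select()] selection over its scores.
#' @param wavenumber the fingerprint axis of the pooled spectra.
#' @param standards list of [glycan_standard()] (default: the synthetic
#'   standards on that axis, via [glycan_standards()]).
#' @param tolerance peak-matching tolerance (default 8 cm^-1).
#' @param min_prominence peak-detection prominence threshold.
#' @return data.frame with one row per (selected PC, standard):
#'   `pc`, `standard`, `correlation`, `sign`, `n_matched`,
#'   `n_reference`.
#' @export
marker_report <- function(pm, selection, wavenumber, standards = NULL,
                          tolerance = 8, min_prominence = 0.05) {
  if (is.null(standards)) standards <- glycan_standards(wavenumber)
  rows <- list()
  for (j in selection$selected) {
    load_j <- ir_spectrum(wavenumber, pm$loadings[, j])
    for (std in standards) {
      sim <- loading_similarity(load_j, std)
      oriented <- ir_spectrum(wavenumber, sim$sign * pm$loadings[, j])
      pk <- detect_peaks(oriented, min_prominence = min_prominence)
      ref <- detect_peaks(crop_fingerprint(std$spectrum,
                                           min(wavenumber), max(wavenumber)),
                          min_prominence = min_prominence)
      mm <- match_peaks(pk, ref, tolerance = tolerance)
      rows[[length(rows) + 1L]] <- data.frame(
        pc = j, standard = std$name, correlation = sim$correlation,
        sign = sim$sign, n_matched = nrow(mm$matches),
        n_reference = nrow(ref))
    }
  }
  do.call(rbind, rows)
}
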