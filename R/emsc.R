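# Modified EMSC digital de-paraffinization.
#
# Each pixel spectrum s is modelled by least squares as
#
#   s = c * m + sum_j a_j p_j + sum_k b_k poly_k + residual
#
# where m is a common target spectrum (mean spectrum of one representative
# tissue image, fixed across the cohort), the p_j are the mean paraffin
# spectrum plus the leading principal-component loadings of a separately
# measured pure-paraffin image (the "interference matrix"), and the poly_k
# are Legendre polynomials up to 4th order on the rescaled axis. The
# corrected spectrum removes the fitted paraffin and baseline terms and
# normalizes by the target scale c, retaining the biomolecular deviation
# from the target. Pixels whose fit is paraffin-dominated are flagged and
# eliminated from downstream statistics.

#' Preprocessing parameters
#'
#' @param sg_window Savitzky-Golay window length (odd, > `sg_order`);
#'   default 11 points.
#' @param sg_order Savitzky-Golay polynomial order; default 3.
#' @param baseline_order polynomial baseline order; default 4.
#' @param q number of paraffin principal-component loadings in the
#'   interference basis (the basis also always contains the mean paraffin
#'   spectrum); default 9, i.e. 10 paraffin columns.
#' @param paraffin_fraction_threshold flag a pixel as paraffin-dominated
#'   when its fitted paraffin fraction exceeds this; default 0.75.
#' @param c_min minimum admissible target scale; pixels with `|c| < c_min`
#'   are flagged (divide-by-near-zero guard); default 0.1.
#' @param fingerprint fingerprint crop window in cm^-1.
#' @return object of class `preprocess_params`.
#' @export
preprocess_params <- function(sg_window = 11L, sg_order = 3L,
                              baseline_order = 4L, q = 9L,
                              paraffin_fraction_threshold = 0.75,
                              c_min = 0.1, fingerprint = fingerprint_window()) {
  if (sg_window %% 2L == 0L || sg_window <= sg_order)
    stop("sg_window must be odd and greater than sg_order", call. = FALSE)
  structure(list(sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 baseline_order = as.integer(baseline_order),
                 q = as.integer(q),
                 paraffin_fraction_threshold = paraffin_fraction_threshold,
                 c_min = c_min, fingerprint = fingerprint),
            class = "preprocess_params")
}

#' Build the paraffin interference basis
#'
#' Mean spectrum plus the first `q` principal-component loadings of the
#' mean-centered pixel spectra of a pure paraffin image. Loadings are
#' orthonormal. If the image rank supports fewer than `q` components the
#' basis is reduced with a warning; components explaining less than
#' `var_floor` of the paraffin variance are dropped as noise directions
#' (a noise-direction column would absorb tissue signal rather than
#' paraffin variability).
#'
#' @param paraffin_image a [hyper_image()] of pure paraffin.
#' @param q number of principal-component loadings requested.
#' @param var_floor minimum explained-variance fraction for a component
#'   to enter the basis (default 0.01).
#' @return object of class `interference_basis` with `mean_paraffin`,
#'   `components` (bands x q matrix), `q` and `wavenumber`.
#' @export
build_paraffin_basis <- function(paraffin_image, q = 9L, var_floor = 0.01) {
  stopifnot(inherits(paraffin_image, "hyper_image"))
  S <- as_spectra_matrix(paraffin_image)$spectra
  if (nrow(S) < q + 1L)
    stop("paraffin image must have at least q + 1 valid pixels", call. = FALSE)
  mu <- colMeans(S)
  Sc <- sweep(S, 2L, mu)
  sv <- svd(Sc, nu = 0L, nv = min(q, ncol(Sc)))
  tol <- max(dim(Sc)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r < q) {
    warning(sprintf("paraffin image rank %d < q = %d; basis reduced", r, q))
    q <- max(r, 0L)
  }
  if (q > 0L) {
    frac <- sv$d^2 / sum(sv$d^2)
    q_floor <- sum(frac[seq_len(q)] >= var_floor)
    if (q_floor < q) {
      message(sprintf(
        "paraffin basis: keeping %d of %d components above the %g variance floor",
        q_floor, q, var_floor))
      q <- max(q_floor, min(1L, q))
    }
  }
  comps <- if (q > 0L) sv$v[, seq_len(q), drop = FALSE]
           else matrix(numeric(), ncol(Sc), 0L)
  structure(list(mean_paraffin = mu, components = comps, q = q,
                 explained = if (length(sv$d)) sv$d^2 / sum(sv$d^2) else numeric(),
                 wavenumber = paraffin_image$wavenumber),
            class = "interference_basis")
}

#' Assemble the EMSC design
#'
#' Columns: effective target spectrum, mean paraffin, `q` paraffin
#' loadings, and Legendre polynomials of degree 0..`baseline_order` on
#' the rescaled axis. The effective target is the supplied target made
#' orthogonal to the paraffin columns (a tissue-image mean carries
#' paraffin itself; orthogonalizing makes corrected output paraffin-free
#' while leaving the model span unchanged). Full column
#' rank is verified at build time; rank deficiency is reported with the
#' names of the collinear columns.
#'
#' @param target the common target spectrum (an [ir_spectrum()] or numeric
#'   vector on the basis axis).
#' @param basis an [build_paraffin_basis()] interference basis.
#' @param baseline_order polynomial baseline order (default 4).
#' @return object of class `emsc_model`.
#' @export
build_emsc_model <- function(target, basis, baseline_order = 4L) {
  stopifnot(inherits(basis, "interference_basis"))
  m <- as_absorbance(target)
  if (inherits(target, "ir_spectrum") &&
      !isTRUE(all.equal(target$wavenumber, basis$wavenumber)))
    stop("target and interference basis must share one axis", call. = FALSE)
  if (length(m) != length(basis$wavenumber))
    stop("target length does not match the basis axis", call. = FALSE)
  P <- legendre_basis(basis$wavenumber, baseline_order)
  # The supplied target is a measured tissue-image mean and therefore
  # carries paraffin itself. The effective target is its residual after
  # projecting out the paraffin columns only: the least-squares span is
  # unchanged, but corrected spectra become paraffin-free instead of
  # normalized to the target's own paraffin content. (The baseline
  # columns are not projected out -- broad tissue structure in the
  # target is signal, not baseline.)
  PP <- cbind(paraffin_mean = basis$mean_paraffin, basis$components)
  if (basis$q > 0L)
    colnames(PP)[1L + seq_len(basis$q)] <- paste0("paraffin_pc", seq_len(basis$q))
  # the mean paraffin spectrum can lie inside the span of the centered
  # loadings (scale variation); drop dependent interference columns,
  # keeping the span intact
  qrPP <- qr(PP)
  if (qrPP$rank < ncol(PP)) {
    keep <- sort(qrPP$pivot[seq_len(qrPP$rank)])
    message("interference columns reduced to an independent set (",
            ncol(PP) - qrPP$rank, " dropped)")
    PP <- PP[, keep, drop = FALSE]
  }
  m_perp <- qr.resid(qr(PP), m)
  if (sqrt(sum(m_perp^2)) < 1e-8 * sqrt(sum(m^2)))
    stop("EMSC design is rank deficient; collinear columns: target lies in ",
         "the paraffin interference span", call. = FALSE)
  D <- cbind(target = m_perp, PP, P)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop("EMSC design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  idx <- list(target = 1L, paraffin = 1L + seq_len(ncol(PP)),
              baseline = (ncol(PP) + 2L):ncol(D))
  structure(list(design = D, qr = qrD, target = m_perp, target_raw = m,
                 basis = basis,
                 baseline_order = as.integer(baseline_order),
                 wavenumber = basis$wavenumber, idx = idx),
            class = "emsc_model")
}

# batch least-squares fit + correction for a matrix of spectra (rows)
emsc_correct_matrix <- function(model, S) {
  stopifnot(inherits(model, "emsc_model"), ncol(S) == length(model$target))
  cf <- t(qr.coef(model$qr, t(S)))            # n x k
  colnames(cf) <- colnames(model$design)
  ip <- model$idx$paraffin
  ib <- model$idx$baseline
  paraffin_part <- cf[, ip, drop = FALSE] %*% t(model$design[, ip, drop = FALSE])
  baseline_part <- cf[, ib, drop = FALSE] %*% t(model$design[, ib, drop = FALSE])
  cc <- cf[, 1L]
  corrected <- (S - paraffin_part - baseline_part) / cc
  fitted <- cc * tcrossprod(rep(1, nrow(S)), model$target) +
    paraffin_part + baseline_part
  residual_norm <- sqrt(rowSums((S - fitted)^2))
  np <- sqrt(rowSums(paraffin_part^2))
  nt <- abs(cc) * sqrt(sum(model$target^2))
  paraffin_fraction <- ifelse(nt + np > 0, np / (nt + np), 1)
  list(coefficients = cf, corrected = corrected,
       residual_norm = residual_norm, paraffin_fraction = paraffin_fraction)
}

#' Fit the EMSC model to one spectrum
#'
#' @param model an [build_emsc_model()] model.
#' @param s an [ir_spectrum()] or numeric vector on the model axis.
#' @param c_min minimum admissible target scale; below it the corrected
#'   spectrum is marked invalid.
#' @return list with `fit` (class `emsc_fit`: coefficients `c`, `a`
#'   (paraffin), `b` (baseline), `residual_norm`, `paraffin_fraction`,
#'   `valid`) and `corrected` (an [ir_spectrum()], or `NULL` when
#'   invalid).
#' @export
fit_emsc <- function(model, s, c_min = 0.1) {
  y <- as_absorbance(s)
  r <- emsc_correct_matrix(model, matrix(y, 1L))
  cc <- unname(r$coefficients[1L, 1L])
  valid <- is.finite(cc) && abs(cc) >= c_min
  fit <- structure(list(c = cc,
                        a = r$coefficients[1L, model$idx$paraffin],
                        b = r$coefficients[1L, model$idx$baseline],
                        residual_norm = r$residual_norm[1L],
                        paraffin_fraction = r$paraffin_fraction[1L],
                        valid = valid),
                   class = "emsc_fit")
  corrected <- if (valid) ir_spectrum(model$wavenumber, r$corrected[1L, ]) else NULL
  list(fit = fit, corrected = corrected)
}

#' Flag paraffin-dominated pixels
#'
#' A pixel is flagged when its fitted paraffin fraction exceeds the
#' threshold, when the target scale `|c|` falls below `c_min`, or when the
#' fit is not finite. Flagged pixels are removed from the validity mask
#' and rendered white in cluster maps.
#'
#' @param fits per-pixel fit table: a data.frame (or list) with columns
#'   `c` and `paraffin_fraction`, as produced by [preprocess_image()].
#' @param params a [preprocess_params()].
#' @return logical vector, `TRUE` = eliminate.
#' @export
flag_paraffin_pixels <- function(fits, params = preprocess_params()) {
  cc <- fits$c
  pf <- fits$paraffin_fraction
  !is.finite(cc) | !is.finite(pf) |
    pf > params$paraffin_fraction_threshold | abs(cc) < params$c_min
}
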