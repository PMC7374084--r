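# Smoothing, fingerprint cropping and the per-image preprocessing chain:
# smooth -> EMSC fit/correct on the full measured axis -> paraffin-pixel
# flagging -> fingerprint crop. EMSC runs on the full axis because the
# strongest paraffin bands (2800-3000 cm^-1) lie outside the fingerprint
# and sharpen the identification of paraffin-dominated pixels.

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (default: 3rd order, 11-point
#' window). Interior points are local polynomial estimates; edge points
#' use the polynomial fits of the edge windows, so polynomials up to the
#' filter order are reproduced exactly everywhere.
#'
#' @param x an [ir_spectrum()], numeric vector, matrix of spectra (rows),
#'   or [hyper_image()].
#' @param window odd window length, greater than `order` and at most the
#'   axis length.
#' @param order polynomial order.
#' @return same kind of object as `x`, smoothed along the spectral axis.
#' @export
smooth_sg <- function(x, window = 11L, order = 3L) {
  UseMethod("smooth_sg")
}

check_sg <- function(n, window, order) {
  if (window %% 2L == 0L || window <= order)
    stop("window must be odd and greater than order", call. = FALSE)
  if (window > n)
    stop("window must not exceed the axis length", call. = FALSE)
}

#' @export
smooth_sg.default <- function(x, window = 11L, order = 3L) {
  check_sg(length(x), window, order)
  as.numeric(signal::sgolayfilt(as.numeric(x), p = order, n = window))
}

#' @export
smooth_sg.ir_spectrum <- function(x, window = 11L, order = 3L) {
  ir_spectrum(x$wavenumber, smooth_sg.default(x$absorbance, window, order))
}

# Savitzky-Golay filtering is linear, so smoothing many spectra of one
# length is a single matrix product with a cached operator built by
# filtering the identity.
.sg_cache <- new.env(parent = emptyenv())

sg_operator <- function(len, window, order) {
  key <- paste(len, window, order, sep = "_")
  if (is.null(.sg_cache[[key]])) {
    I <- diag(len)
    .sg_cache[[key]] <- apply(I, 2L, signal::sgolayfilt, p = order, n = window)
  }
  .sg_cache[[key]]
}

#' @export
smooth_sg.matrix <- function(x, window = 11L, order = 3L) {
  check_sg(ncol(x), window, order)
  x %*% t(sg_operator(ncol(x), window, order))
}

#' @export
smooth_sg.hyper_image <- function(x, window = 11L, order = 3L) {
  d <- dim(x$cube)
  S <- smooth_sg.matrix(matrix(x$cube, d[1L] * d[2L], d[3L]), window, order)
  hyper_image(array(S, d), x$wavenumber, x$valid_mask, x$pixel_size)
}

#' Crop to the fingerprint window
#'
#' Restricts the axis (inclusive) to `lo <= wavenumber <= hi`; default
#' 1000-1800 cm^-1, the biomolecular fingerprint used for segmentation
#' and classification.
#'
#' @param x an [ir_spectrum()] or [hyper_image()].
#' @param lo,hi window bounds in cm^-1.
#' @return same kind of object, cropped.
#' @export
crop_fingerprint <- function(x, lo = 1000, hi = 1800) {
  UseMethod("crop_fingerprint")
}

crop_index <- function(wavenumber, lo, hi) {
  i <- which(wavenumber >= lo & wavenumber <= hi)
  if (!length(i))
    stop("fingerprint crop [", lo, ", ", hi, "] is empty on this axis",
         call. = FALSE)
  i
}

#' @export
crop_fingerprint.ir_spectrum <- function(x, lo = 1000, hi = 1800) {
  i <- crop_index(x$wavenumber, lo, hi)
  ir_spectrum(x$wavenumber[i], x$absorbance[i])
}

#' @export
crop_fingerprint.hyper_image <- function(x, lo = 1000, hi = 1800) {
  i <- crop_index(x$wavenumber, lo, hi)
  hyper_image(x$cube[, , i, drop = FALSE], x$wavenumber[i],
              x$valid_mask, x$pixel_size)
}

#' Common target spectrum from a representative image
#'
#' The EMSC target is the mean spectrum of one designated representative
#' tissue image, smoothed with the configured Savitzky-Golay filter, and
#' is used unchanged for every sample of a cohort.
#'
#' @param img the representative [hyper_image()].
#' @param params a [preprocess_params()].
#' @return an [ir_spectrum()].
#' @export
target_spectrum <- function(img, params = preprocess_params()) {
  smooth_sg(image_mean_spectrum(img), params$sg_window, params$sg_order)
}

#' Preprocess a hyperspectral image
#'
#' Runs the full per-image chain: Savitzky-Golay smoothing, EMSC
#' fit/correction on the full measured axis, flagging and elimination of
#' paraffin-dominated pixels, then fingerprint cropping. The chain is
#' deterministic.
#'
#' @param img the raw [hyper_image()].
#' @param model an [build_emsc_model()] model on the image axis.
#' @param params a [preprocess_params()].
#' @return object of class `preprocessed_image`: list with `image` (the
#'   corrected, cropped [hyper_image()] whose validity mask excludes
#'   flagged pixels), `fits` (per-pixel data.frame: `row`, `col`, `c`,
#'   paraffin and baseline coefficients, `residual_norm`,
#'   `paraffin_fraction`, `flagged`), `flagged_mask`, `params`.
#' @export
preprocess_image <- function(img, model, params = preprocess_params()) {
  stopifnot(inherits(img, "hyper_image"), inherits(model, "emsc_model"))
  if (!isTRUE(all.equal(img$wavenumber, model$wavenumber)))
    stop("image and EMSC model axes are incompatible", call. = FALSE)
  px <- as_spectra_matrix(img)
  S <- smooth_sg(px$spectra, params$sg_window, params$sg_order)
  fit <- emsc_correct_matrix(model, S)
  fits <- data.frame(px$coords,
                     c = fit$coefficients[, 1L],
                     fit$coefficients[, -1L, drop = FALSE],
                     residual_norm = fit$residual_norm,
                     paraffin_fraction = fit$paraffin_fraction,
                     check.names = FALSE)
  flagged <- flag_paraffin_pixels(fits, params)
  fits$flagged <- flagged
  d <- dim(img$cube)
  flagged_mask <- matrix(FALSE, d[1L], d[2L])
  flagged_mask[cbind(px$coords$row, px$coords$col)] <- flagged
  valid <- img$valid_mask & !flagged_mask
  cube <- array(NA_real_, d)
  keep <- !flagged
  idx <- cbind(px$coords$row[keep], px$coords$col[keep])
  for (k in seq_len(d[3L]))
    cube[cbind(idx, k)] <- fit$corrected[keep, k]
  out <- hyper_image(cube, img$wavenumber, valid, img$pixel_size)
  out <- crop_fingerprint(out, params$fingerprint[1L], params$fingerprint[2L])
  structure(list(image = out, fits = fits, flagged_mask = flagged_mask,
                 params = params),
            class = "preprocessed_image")
}

#' @export
print.preprocessed_image <- function(x, ...) {
  cat(sprintf("<preprocessed_image> %d pixels fit, %d flagged as paraffin\n",
              nrow(x$fits), sum(x$fits$flagged)))
  print(x$image)
  invisible(x)
}
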