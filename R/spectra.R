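#' Construct a single IR spectrum
#'
#' A spectrum is a pair of a strictly increasing wavenumber axis (cm^-1)
#' and one absorbance value per axis point.
#'
#' @param wavenumber numeric axis in cm^-1, strictly increasing, positive.
#' @param absorbance numeric absorbance values, same length as the axis.
#' @return object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavenumber, absorbance) {
  wavenumber <- check_axis(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != length(wavenumber))
    stop("absorbance and wavenumber must have the same length", call. = FALSE)
  if (any(!is.finite(absorbance)))
    stop("absorbance values must all be finite", call. = FALSE)
  structure(list(wavenumber = wavenumber, absorbance = absorbance),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %.0f-%.0f cm-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

as_absorbance <- function(s) {
  if (inherits(s, "ir_spectrum")) s$absorbance else as.numeric(s)
}

#' Construct a hyperspectral image
#'
#' The central container of the pipeline: a height x width x bands
#' absorbance cube with its wavenumber axis and a per-pixel validity mask.
#' Pixels with `valid_mask = FALSE` are never consumed by downstream
#' statistics.
#'
#' @param cube numeric array `c(height, width, bands)`.
#' @param wavenumber axis of length `bands`.
#' @param valid_mask logical `height x width` matrix; defaults to all `TRUE`.
#' @param pixel_size pixel edge length in micrometres (metadata only).
#' @return object of class `hyper_image`.
#' @export
hyper_image <- function(cube, wavenumber, valid_mask = NULL, pixel_size = 5.5) {
  wavenumber <- check_axis(wavenumber)
  d <- dim(cube)
  if (length(d) != 3L)
    stop("cube must be a 3-d array (height, width, bands)", call. = FALSE)
  if (d[3L] != length(wavenumber))
    stop("third cube dimension must match the wavenumber axis length", call. = FALSE)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, d[1L], d[2L])
  if (!is.logical(valid_mask) || !all(dim(valid_mask) == d[1:2]))
    stop("valid_mask must be a logical height x width matrix", call. = FALSE)
  structure(list(cube = cube, wavenumber = wavenumber,
                 valid_mask = valid_mask, pixel_size = pixel_size),
            class = "hyper_image")
}

#' @export
print.hyper_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<hyper_image> %d x %d pixels, %d bands (%.0f-%.0f cm-1), %d valid\n",
              d[1L], d[2L], d[3L], min(x$wavenumber), max(x$wavenumber),
              sum(x$valid_mask)))
  invisible(x)
}

#' @export
dim.hyper_image <- function(x) dim(x$cube)

#' Pixel spectra of an image as a matrix
#'
#' @param img a `hyper_image`.
#' @param valid_only return only pixels with `valid_mask = TRUE`.
#' @return list with `spectra` (n x bands matrix) and `coords`
#'   (data.frame of `row`, `col` for each returned pixel).
#' @export
as_spectra_matrix <- function(img, valid_only = TRUE) {
  d <- dim(img$cube)
  S <- matrix(img$cube, d[1L] * d[2L], d[3L])
  keep <- if (valid_only) as.vector(img$valid_mask) else rep(TRUE, d[1L] * d[2L])
  idx <- which(keep)
  coords <- data.frame(row = (idx - 1L) %% d[1L] + 1L,
                       col = (idx - 1L) %/% d[1L] + 1L)
  list(spectra = S[idx, , drop = FALSE], coords = coords)
}

#' Mean spectrum over valid pixels
#'
#' @param img a `hyper_image`.
#' @return an `ir_spectrum`.
#' @export
image_mean_spectrum <- function(img) {
  m <- as_spectra_matrix(img)
  ir_spectrum(img$wavenumber, colMeans(m$spectra))
}

#' Resample a spectrum onto a target axis
#'
#' Linear interpolation; exact at shared grid points. Extrapolation beyond
#' the source range is refused.
#'
#' @param s an `ir_spectrum`.
#' @param target numeric target axis (strictly increasing).
#' @return an `ir_spectrum` on the target axis.
#' @export
resample_spectrum <- function(s, target) {
  stopifnot(inherits(s, "ir_spectrum"))
  target <- check_axis(target)
  if (min(target) < min(s$wavenumber) || max(target) > max(s$wavenumber))
    stop("target axis extends beyond the source range (extrapolation refused)",
         call. = FALSE)
  y <- stats::approx(s$wavenumber, s$absorbance, xout = target)$y
  ir_spectrum(target, y)
}
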