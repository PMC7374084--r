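# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

check_axis <- function(wavenumber) {
  if (!is.numeric(wavenumber) || length(wavenumber) < 2L)
    stop("wavenumber axis must be numeric with at least 2 points", call. = FALSE)
  if (any(!is.finite(wavenumber)) || any(wavenumber <= 0))
    stop("wavenumber axis values must be finite and positive", call. = FALSE)
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  invisible(as.numeric(wavenumber))
}

#' Default measurement axis
#'
#' Wavenumber grid covering the measured mid-IR range 1000-3800 cm^-1.
#' The instrument resolution is 8 cm^-1; the default point spacing of
#' 4 cm^-1 gives two points per resolution element (701 points).
#'
#' @param step point spacing in cm^-1.
#' @return numeric vector of wavenumbers, strictly increasing.
#' @export
default_axis <- function(step = 4) seq(1000, 3800, by = step)

#' Fingerprint window bounds (cm^-1)
#'
#' The biomolecular fingerprint region used for segmentation and
#' classification.
#' @export
fingerprint_window <- function() c(1000, 1800)

gaussian_band <- function(wavenumber, center, sd, amplitude) {
  amplitude * exp(-0.5 * ((wavenumber - center) / sd)^2)
}

# Legendre polynomials (orthogonal on [-1,1]) evaluated on the axis rescaled
# to [-1,1]; used for the EMSC baseline block and the synthetic baselines.
legendre_basis <- function(wavenumber, order) {
  x <- 2 * (wavenumber - min(wavenumber)) / (max(wavenumber) - min(wavenumber)) - 1
  P <- matrix(0, length(x), order + 1L)
  P[, 1L] <- 1
  if (order >= 1L) P[, 2L] <- x
  if (order >= 2L) {
    for (k in 2:order) P[, k + 1L] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1L]) / k
  }
  colnames(P) <- paste0("poly", 0:order)
  P
}

# separable gaussian blur with reflected edges; used for scene layout fields
blur2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(v[seq(min(r, n), 1L)], v, v[seq(n, max(1L, n - r + 1L))])
    if (length(vp) < n + 2L * r) vp <- c(rep(v[1L], n + 2L * r - length(vp)), vp)
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1L):(r + n)]
  }
  m2 <- apply(m, 2L, conv1)
  t(apply(m2, 1L, conv1))
}
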