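# ENVI cube input/output.
#
# Dialect written by this package: text header `<base>.hdr`, float32
# band-sequential binary `<base>.img`, little endian, wavelengths in cm^-1
# in the header `wavelength` field. The validity mask, which ENVI has no
# standard field for, is persisted as a 0/255 PNG sidecar `<base>_mask.png`.

envi_base <- function(path) sub("\\.(hdr|img|raw)$", "", path)

#' Write a hyperspectral cube as an ENVI file pair
#'
#' Writes `<path>.hdr` (text header) and `<path>.img` (float32 BSQ binary),
#' plus a `<path>_mask.png` sidecar when any pixel is invalid.
#'
#' @param img a [hyper_image()].
#' @param path output path; any `.hdr`/`.img` extension is stripped.
#' @return the header path, invisibly.
#' @export
write_envi_cube <- function(img, path) {
  stopifnot(inherits(img, "hyper_image"))
  base <- envi_base(path)
  d <- dim(img$cube)
  hdr <- c(
    "ENVI",
    "description = {spechist hyperspectral cube}",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = cm-1",
    sprintf("pixel size = %g", img$pixel_size),
    paste0("wavelength = {", paste(format(img$wavenumber, trim = TRUE,
                                          digits = 12), collapse = ", "), "}")
  )
  writeLines(hdr, paste0(base, ".hdr"))
  con <- file(paste0(base, ".img"), "wb")
  on.exit(close(con))
  # BSQ: per band, line (row) major
  for (k in seq_len(d[3L]))
    writeBin(as.numeric(t(img$cube[, , k])), con, size = 4L, endian = "little")
  if (!all(img$valid_mask))
    png::writePNG(ifelse(img$valid_mask, 1, 0), paste0(base, "_mask.png"))
  invisible(paste0(base, ".hdr"))
}

parse_envi_header <- function(hdr_path) {
  if (!file.exists(hdr_path))
    stop("ENVI header not found: ", hdr_path, call. = FALSE)
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_field <- function(name, required = TRUE) {
    m <- regmatches(txt, regexpr(paste0("(?mi)^\\s*", name,
                                        "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"),
                                 txt, perl = TRUE))
    if (!length(m)) {
      if (required)
        stop("ENVI header is missing required field '", name, "'", call. = FALSE)
      return(NULL)
    }
    val <- sub(paste0("(?i)^\\s*", name, "\\s*=\\s*"), "", m[[1L]], perl = TRUE)
    gsub("^\\{|\\}$", "", trimws(gsub("\n", " ", val)))
  }
  num_field <- function(name) {
    v <- suppressWarnings(as.numeric(get_field(name)))
    if (is.na(v)) stop("ENVI header field '", name, "' is not numeric", call. = FALSE)
    v
  }
  wl <- suppressWarnings(as.numeric(trimws(strsplit(get_field("wavelength"), ",")[[1L]])))
  if (any(is.na(wl)))
    stop("ENVI header field 'wavelength' is not numeric", call. = FALSE)
  list(samples = num_field("samples"), lines = num_field("lines"),
       bands = num_field("bands"), data_type = num_field("data type"),
       interleave = tolower(get_field("interleave")),
       byte_order = num_field("byte order"),
       wavelength = wl,
       pixel_size = suppressWarnings(as.numeric(get_field("pixel size",
                                                          required = FALSE))))
}

#' Read an ENVI hyperspectral cube
#'
#' Accepts BSQ, BIL and BIP interleaves and float32/float64 data types.
#' The axis is taken from the header `wavelength` list; if the header
#' stores wavelengths descending, the axis is sorted ascending and the
#' bands reordered consistently. A `<base>_mask.png` sidecar, if present,
#' restores the validity mask.
#'
#' @param path path to the `.hdr` file, the binary, or the common base name.
#' @return a [hyper_image()].
#' @export
read_envi_cube <- function(path) {
  base <- envi_base(path)
  h <- parse_envi_header(paste0(base, ".hdr"))
  bin <- paste0(base, ".img")
  if (!file.exists(bin)) bin <- paste0(base, ".raw")
  if (!file.exists(bin))
    stop("ENVI binary not found for header: ", base, call. = FALSE)
  n <- h$samples * h$lines * h$bands
  size <- if (h$data_type == 4) 4L else if (h$data_type == 5) 8L else
    stop("unsupported ENVI data type: ", h$data_type, call. = FALSE)
  endian <- if (h$byte_order == 0) "little" else "big"
  v <- readBin(bin, "numeric", n = n, size = size, endian = endian)
  if (length(v) != n)
    stop("ENVI binary is truncated: expected ", n, " values, read ", length(v),
         call. = FALSE)
  cube <- switch(h$interleave,
    bsq = aperm(array(v, c(h$samples, h$lines, h$bands)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(h$samples, h$bands, h$lines)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(h$bands, h$samples, h$lines)), c(3L, 2L, 1L)),
    stop("unsupported ENVI interleave: ", h$interleave, call. = FALSE))
  wl <- h$wavelength
  if (length(wl) != h$bands)
    stop("ENVI wavelength list length does not match bands", call. = FALSE)
  ord <- order(wl)
  wl <- wl[ord]
  cube <- cube[, , ord, drop = FALSE]
  mask_path <- paste0(base, "_mask.png")
  valid <- NULL
  if (file.exists(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    valid <- m > 0.5
  }
  ps <- h$pixel_size
  if (is.null(ps) || !length(ps) || is.na(ps)) ps <- 5.5
  hyper_image(cube, wl, valid_mask = valid, pixel_size = ps)
}
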