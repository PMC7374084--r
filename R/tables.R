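# CSV spectra tables: rows are spectra, columns are wavenumbers, with
# leading sample_id and class_label columns. This "database of spectra"
# layout streams well and is what the classification stage consumes.

#' Read a CSV spectra table
#'
#' Expected header: `sample_id`, `class_label`, then one numeric wavenumber
#' per remaining column, strictly increasing. Rows containing non-numeric
#' intensities are rejected with their row indices reported.
#'
#' @param path CSV file path.
#' @return object of class `spectra_table`: a list with `sample_id`,
#'   `class_label`, `wavenumber` and the `spectra` matrix (one row per
#'   spectrum).
#' @export
read_spectra_table <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  nm <- names(dt)
  if (length(nm) < 3L || nm[1L] != "sample_id" || nm[2L] != "class_label")
    stop("spectra table must start with columns 'sample_id', 'class_label'",
         call. = FALSE)
  wn <- suppressWarnings(as.numeric(nm[-(1:2)]))
  if (any(is.na(wn)))
    stop("spectra table wavenumber columns are not numeric", call. = FALSE)
  if (any(diff(wn) <= 0))
    stop("spectra table wavenumber header must be strictly increasing",
         call. = FALSE)
  if (nrow(dt) == 0L)
    return(structure(list(sample_id = character(), class_label = character(),
                          wavenumber = wn,
                          spectra = matrix(numeric(), 0L, length(wn),
                                           dimnames = list(NULL, nm[-(1:2)]))),
                     class = "spectra_table"))
  vals <- as.matrix(dt[, -(1:2)])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(rowSums(!is.finite(num)) > 0L)
  if (length(bad))
    stop("non-numeric intensities in spectra table rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  colnames(num) <- nm[-(1:2)]
  structure(list(sample_id = dt[["sample_id"]],
                 class_label = dt[["class_label"]],
                 wavenumber = wn, spectra = num),
            class = "spectra_table")
}

#' Write a CSV spectra table
#'
#' Inverse of [read_spectra_table()]. Numbers are written in shortest
#' round-trip decimal form, so write -> read -> write is byte-stable.
#'
#' @param tbl a `spectra_table`, or a list with fields `sample_id`,
#'   `class_label`, `wavenumber`, `spectra`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(tbl, path) {
  stopifnot(length(tbl$sample_id) == nrow(tbl$spectra),
            length(tbl$wavenumber) == ncol(tbl$spectra))
  dt <- data.table::data.table(sample_id = tbl$sample_id,
                               class_label = tbl$class_label)
  sp <- data.table::as.data.table(tbl$spectra)
  data.table::setnames(sp, format(tbl$wavenumber, trim = TRUE, digits = 12))
  data.table::fwrite(cbind(dt, sp), path)
  invisible(path)
}

#' Convert sample records to a spectra table
#'
#' @param records list of [sample_record()] objects.
#' @return a `spectra_table` with one row per pixel spectrum; `class_label`
#'   carries the pathology label.
#' @export
records_to_table <- function(records) {
  spectra <- do.call(rbind, lapply(records, `[[`, "spectra"))
  structure(list(
    sample_id = rep(vapply(records, `[[`, "", "sample_id"),
                    vapply(records, function(r) nrow(r$spectra), 0L)),
    class_label = rep(vapply(records, `[[`, "", "pathology"),
                      vapply(records, function(r) nrow(r$spectra), 0L)),
    wavenumber = records[[1L]]$wavenumber,
    spectra = spectra), class = "spectra_table")
}
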