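#' Spectral dataset container
#'
#' A `spectra_set` holds a rectangular absorbance matrix on a shared,
#' strictly increasing wavelength grid together with per-sample metadata.
#' It is the object every stage of the pipeline consumes and produces.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing (duplicates are an error). Rows of `absorbance` are
#'   reordered if the input grid is unsorted.
#' @param absorbance Numeric matrix, samples x wavelengths, all finite.
#' @param meta Data frame with one row per spectrum. Recognised columns:
#'   `sample_id` (character), `germination_h` (integer hours, multiples of
#'   6 in \[0, 120\], or `NA`), `replicate` (integer >= 1), `scan`
#'   (integer >= 1), `mode` (`"transmission"` or `"reflectance"`),
#'   `analyte_conc` (mg/L, optional, for standard solutions).
#'
#' @return An object of class `spectra_set` with elements `wavelengths`,
#'   `absorbance` and `meta`.
#' @export
spectra_set <- function(wavelengths, absorbance, meta = NULL) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  ord <- order(wavelengths)
  wavelengths <- wavelengths[ord]
  absorbance <- absorbance[, ord, drop = FALSE]
  if (is.null(meta)) {
    meta <- data.frame(sample_id = sprintf("s%03d", seq_len(nrow(absorbance))),
                       stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  x <- structure(list(wavelengths = wavelengths,
                      absorbance = absorbance,
                      meta = meta),
                 class = "spectra_set")
  validate_spectra_set(x)
  x
}

#' @rdname spectra_set
#' @param x A `spectra_set`.
#' @export
validate_spectra_set <- function(x) {
  wl <- x$wavelengths
  ab <- x$absorbance
  if (anyDuplicated(wl))
    spst_error(sprintf("duplicate wavelengths in grid (e.g. %.6g nm)",
                       wl[duplicated(wl)][1L]), "sproutspec_duplicate_wavelength")
  if (length(wl) >= 2L && any(diff(wl) <= 0))
    spst_error("wavelength grid must be strictly increasing", "sproutspec_format_error")
  if (ncol(ab) != length(wl))
    spst_error("absorbance matrix has a column count different from the wavelength grid",
               "sproutspec_format_error")
  if (nrow(x$meta) != nrow(ab))
    spst_error("metadata row count differs from spectrum count", "sproutspec_format_error")
  if (!all(is.finite(ab)))
    spst_error("non-finite absorbance values present", "sproutspec_parse_error")
  gh <- x$meta$germination_h
  if (!is.null(gh)) {
    bad <- !is.na(gh) & (gh %% 6 != 0 | gh < 0 | gh > 120)
    if (any(bad))
      spst_error(sprintf("germination_h must be a multiple of 6 in [0, 120]; got %s",
                         gh[bad][1L]), "sproutspec_format_error")
  }
  invisible(x)
}

#' @export
print.spectra_set <- function(x, ...) {
  wl <- x$wavelengths
  cat(sprintf("<spectra_set> %d spectra x %d wavelengths (%.6g-%.6g nm)\n",
              nrow(x$absorbance), length(wl), min(wl), max(wl)))
  mcols <- setdiff(names(x$meta), "sample_id")
  if (length(mcols)) cat("  metadata:", paste(mcols, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Number of spectra in a set
#' @param x A `spectra_set`.
#' @return Integer count of rows.
#' @export
n_spectra <- function(x) nrow(x$absorbance)

#' Subset a spectra set by rows
#' @param x A `spectra_set`.
#' @param i Row index (logical or integer).
#' @return A `spectra_set` with matching rows of absorbance and metadata.
#' @export
subset_spectra <- function(x, i) {
  spectra_set(x$wavelengths, x$absorbance[i, , drop = FALSE],
              x$meta[i, , drop = FALSE])
}

meta_columns <- c("sample_id", "germination_h", "replicate", "scan", "mode",
                  "analyte_conc")

#' Read spectra from wide-format CSV
#'
#' The dialect is UTF-8, comma-separated, `.` decimal: metadata columns
#' `sample_id, germination_h, replicate, scan, mode[, analyte_conc]`
#' followed by one column per wavelength, named by its nm value.
#'
#' @param path Path to a CSV file.
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path))
    spst_error(sprintf("file not found: %s", path), "sproutspec_io_error")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!("sample_id" %in% names(df)))
    spst_error("missing required header column 'sample_id'", "sproutspec_format_error")
  mnames <- intersect(meta_columns, names(df))
  # no setdiff: duplicated wavelength columns must survive to be rejected
  wnames <- names(df)[!names(df) %in% meta_columns]
  if (!length(wnames))
    spst_error("no wavelength columns found", "sproutspec_format_error")
  wl <- suppressWarnings(as.numeric(wnames))
  if (anyNA(wl))
    spst_error(sprintf("non-numeric wavelength column name: '%s'",
                       wnames[is.na(wl)][1L]), "sproutspec_format_error")
  ab <- as.matrix(df[, wnames, drop = FALSE])
  if (!is.numeric(ab)) {
    bad <- which(!vapply(df[wnames], is.numeric, logical(1L)))[1L]
    row <- which(is.na(suppressWarnings(as.numeric(df[[wnames[bad]]]))))[1L]
    spst_error(sprintf("non-numeric absorbance at row %d, column '%s'",
                       row, wnames[bad]), "sproutspec_parse_error")
  }
  if (anyNA(ab)) {
    idx <- which(is.na(ab), arr.ind = TRUE)[1L, ]
    spst_error(sprintf("non-numeric absorbance at row %d, column '%s'",
                       idx[1L], wnames[idx[2L]]), "sproutspec_parse_error")
  }
  spectra_set(wl, ab, df[, mnames, drop = FALSE])
}

#' Write spectra to wide-format CSV
#'
#' Wavelength column names carry 2 decimals; absorbance values are written
#' with 9 significant digits so that a read/write round trip is numerically
#' lossless at that precision.
#'
#' @param x A `spectra_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  wl_names <- formatC(x$wavelengths, format = "f", digits = 2)
  ab <- x$absorbance
  ab_chr <- matrix(formatC(ab, format = "g", digits = 9), nrow = nrow(ab))
  out <- cbind(x$meta,
               stats::setNames(as.data.frame(ab_chr, stringsAsFactors = FALSE),
                               wl_names))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a spectra set to a wavelength window
#'
#' Keeps exactly the wavelengths `lo_nm <= lambda <= hi_nm` (bounds
#' inclusive, compared with a 1e-9 nm tolerance). Metadata are unchanged
#' and the input set is not modified. The operation is idempotent.
#'
#' @param x A `spectra_set`.
#' @param lo_nm,hi_nm Window bounds in nm, `lo_nm < hi_nm`.
#' @return A `spectra_set` on the retained grid.
#' @export
truncate_spectra <- function(x, lo_nm, hi_nm) {
  if (!(lo_nm < hi_nm))
    spst_error("window requires lo_nm < hi_nm", "sproutspec_config_error")
  tol <- 1e-9
  keep <- x$wavelengths >= lo_nm - tol & x$wavelengths <= hi_nm + tol
  if (!any(keep))
    spst_error(sprintf("window [%g, %g] nm does not intersect the grid",
                       lo_nm, hi_nm), "sproutspec_empty_window")
  spectra_set(x$wavelengths[keep], x$absorbance[, keep, drop = FALSE], x$meta)
}

#' Average consecutive scans or replicates
#'
#' Rows are averaged (arithmetic mean per wavelength) within
#' `(sample_id, replicate)` for `level = "scan"` or within `sample_id`
#' for `level = "replicate"`; the collapsed index is set to 1. Mixed
#' `germination_h` within a group is an error.
#'
#' @param x A `spectra_set`.
#' @param level `"scan"` (collapse scans within replicates) or
#'   `"replicate"` (collapse everything sharing a `sample_id`).
#' @return A `spectra_set` with one row per group, groups in first-occurrence
#'   order.
#' @export
aggregate_scans <- function(x, level = c("scan", "replicate")) {
  level <- match.arg(level)
  m <- x$meta
  if (is.null(m$sample_id))
    spst_error("aggregation requires sample_id metadata", "sproutspec_config_error")
  key <- if (level == "scan") {
    if (is.null(m$replicate))
      spst_error("level 'scan' requires replicate metadata", "sproutspec_config_error")
    paste(m$sample_id, m$replicate, sep = "\r")
  } else m$sample_id
  grp <- factor(key, levels = unique(key))
  gh <- m$germination_h
  if (!is.null(gh)) {
    nvals <- tapply(gh, grp, function(v) length(unique(v)))
    if (any(nvals > 1L))
      spst_error(sprintf("inconsistent germination_h within group '%s'",
                         levels(grp)[which(nvals > 1L)[1L]]),
                 "sproutspec_metadata_conflict")
  }
  ab <- rowsum(x$absorbance, grp, reorder = FALSE) /
    as.vector(table(grp)[levels(grp)])
  first <- match(levels(grp), key)
  meta <- m[first, , drop = FALSE]
  rownames(meta) <- NULL
  if (level == "scan") {
    if (!is.null(meta$scan)) meta$scan <- 1L
  } else {
    if (!is.null(meta$scan)) meta$scan <- 1L
    if (!is.null(meta$replicate)) meta$replicate <- 1L
  }
  spectra_set(x$wavelengths, ab, meta)
}

# classed stop() so callers can distinguish configuration, parse and data
# errors without matching message text
spst_error <- function(msg, class) {
  stop(structure(class = c(class, "sproutspec_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
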