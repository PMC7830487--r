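#' Savitzky-Golay smoothing matrix
#'
#' Builds the n x n linear operator that maps a spectrum to its SG-filtered
#' version. Interior points use the symmetric least-squares convolution
#' coefficients; the first and last `(window - 1) / 2` points fit the local
#' polynomial on the truncated one-sided neighbourhood, which keeps the
#' filter exact on polynomials up to `polyorder` at the edges too.
#'
#' @param n Spectrum length.
#' @param window Odd filter width in points.
#' @param polyorder Degree of the fitted polynomial (`< window`).
#' @param deriv Derivative order (`<= polyorder`); 0 smooths.
#' @param step Grid spacing used to scale derivatives (ignored for
#'   `deriv = 0`). Non-uniform grids are treated as index-spaced.
#' @return An `n` x `n` dense matrix `S` such that `y_out = S %*% y`.
#' @keywords internal
savgol_operator <- function(n, window, polyorder = 2L, deriv = 0L, step = 1) {
  if (window %% 2L != 1L)
    spst_error("Savitzky-Golay window must be odd", "sproutspec_config_error")
  if (polyorder >= window)
    spst_error("Savitzky-Golay window must exceed the polynomial order",
               "sproutspec_config_error")
  if (deriv > polyorder)
    spst_error("derivative order cannot exceed the polynomial order",
               "sproutspec_config_error")
  if (window > n)
    spst_error("Savitzky-Golay window wider than the spectrum",
               "sproutspec_config_error")
  h <- (window - 1L) %/% 2L
  coef_at <- function(offsets) {
    X <- outer(offsets, 0:polyorder, `^`)
    # row deriv+1 of (X'X)^-1 X' gives the fitted poly's deriv-th coefficient
    beta_row <- solve(crossprod(X), t(X))[deriv + 1L, ]
    beta_row * factorial(deriv) / step^deriv
  }
  S <- matrix(0, n, n)
  interior <- coef_at(-h:h)
  for (i in seq_len(n)) {
    if (i > h && i <= n - h) {
      S[i, (i - h):(i + h)] <- interior
    } else {
      j <- max(1L, i - h):min(n, i + h)
      S[i, j] <- coef_at(j - i)
    }
  }
  S
}

#' Savitzky-Golay smoothing of a spectra set
#'
#' Least-squares polynomial convolution filter; exact on polynomials of
#' degree `<= polyorder`. Defaults follow the pretreatment used throughout
#' the package: 15 points, second-order polynomial, no derivative.
#'
#' @param x A [spectra_set()].
#' @param window Odd number of points (default 15).
#' @param polyorder Polynomial degree (default 2).
#' @param deriv Derivative order (default 0).
#' @return A `spectra_set` on the same grid.
#' @export
savgol_smooth <- function(x, window = 15L, polyorder = 2L, deriv = 0L) {
  wl <- x$wavelengths
  step <- if (length(wl) > 1L) stats::median(diff(wl)) else 1
  S <- savgol_operator(length(wl), as.integer(window), as.integer(polyorder),
                       as.integer(deriv), step)
  spectra_set(wl, x$absorbance %*% t(S), x$meta)
}

#' Standard normal variate transform
#'
#' Each spectrum is centred and scaled to unit variance:
#' `(x - mean(x)) / sd(x)` with the sample (n - 1) standard deviation.
#' This removes additive offsets and multiplicative scatter per spectrum,
#' so the output is invariant under per-row affine maps with positive scale.
#'
#' @param x A [spectra_set()].
#' @return A `spectra_set` whose rows have mean 0 and sd 1.
#' @export
snv <- function(x) {
  ab <- x$absorbance
  mu <- rowMeans(ab)
  sdv <- sqrt(rowSums((ab - mu)^2) / (ncol(ab) - 1L))
  if (any(sdv == 0)) {
    bad <- which(sdv == 0)[1L]
    id <- if (!is.null(x$meta$sample_id)) x$meta$sample_id[bad] else bad
    spst_error(sprintf("constant spectrum (sd = 0) for sample '%s'", id),
               "sproutspec_degenerate_spectrum")
  }
  spectra_set(x$wavelengths, (ab - mu) / sdv, x$meta)
}

#' Preprocessing configuration
#'
#' @param sg_window Odd SG width in points (default 15).
#' @param sg_polyorder SG polynomial degree (default 2).
#' @param sg_derivative SG derivative order (default 0).
#' @param apply_snv Apply SNV after smoothing (default `TRUE`).
#' @param window_lo_nm,window_hi_nm Truncation window in nm applied before
#'   smoothing; `NULL` keeps the full grid. The first O-H overtone window
#'   used for aquaphotomics is 1300-1600 nm; the wide window is 950-1630 nm.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 15L, sg_polyorder = 2L,
                              sg_derivative = 0L, apply_snv = TRUE,
                              window_lo_nm = NULL, window_hi_nm = NULL) {
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window %% 2L != 1L || sg_window <= sg_polyorder)
    spst_error("sg_window must be odd and greater than sg_polyorder",
               "sproutspec_config_error")
  if (sg_derivative > sg_polyorder)
    spst_error("sg_derivative must not exceed sg_polyorder",
               "sproutspec_config_error")
  structure(list(sg_window = sg_window, sg_polyorder = sg_polyorder,
                 sg_derivative = as.integer(sg_derivative),
                 apply_snv = isTRUE(apply_snv),
                 window_lo_nm = window_lo_nm, window_hi_nm = window_hi_nm),
            class = "preprocess_config")
}

#' Full spectral pretreatment chain
#'
#' Applies, in order: wavelength truncation, Savitzky-Golay smoothing,
#' then (optionally) SNV. The order is fixed; applying the chain twice is
#' not the same as applying it once because SNV renormalises the smoothed
#' rows. The applied steps are recorded in the `"preprocess_steps"`
#' attribute of the result as an audit trail.
#'
#' @param x A [spectra_set()].
#' @param cfg A [preprocess_config()].
#' @return A preprocessed `spectra_set` with a `"preprocess_steps"`
#'   character attribute.
#' @export
preprocess_pipeline <- function(x, cfg = preprocess_config()) {
  steps <- character()
  if (!is.null(cfg$window_lo_nm) && !is.null(cfg$window_hi_nm)) {
    x <- truncate_spectra(x, cfg$window_lo_nm, cfg$window_hi_nm)
    steps <- c(steps, sprintf("truncate[%g,%g]nm", cfg$window_lo_nm,
                              cfg$window_hi_nm))
  }
  x <- savgol_smooth(x, cfg$sg_window, cfg$sg_polyorder, cfg$sg_derivative)
  steps <- c(steps, sprintf("savgol(window=%d,poly=%d,deriv=%d)",
                            cfg$sg_window, cfg$sg_polyorder, cfg$sg_derivative))
  if (cfg$apply_snv) {
    x <- snv(x)
    steps <- c(steps, "snv")
  }
  attr(x, "preprocess_steps") <- steps
  x
}
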