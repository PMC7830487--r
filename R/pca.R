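#' Principal component analysis of spectra
#'
#' PCA by singular value decomposition of the mean-centred absorbance
#' matrix. No column autoscaling is applied: SNV pretreatment already
#' row-normalises the spectra, and variance scaling would inflate quiet
#' spectral regions. Loadings follow the sign convention that each
#' loading's largest-magnitude element is positive.
#'
#' @param x A [spectra_set()] or a numeric matrix (samples x variables).
#' @param n_pcs Number of components to retain.
#' @return A `pca_model` with elements `center` (mean spectrum), `loadings`
#'   (variables x n_pcs, orthonormal), `scores` (samples x n_pcs),
#'   `explained_var_pct` (per retained PC, out of the total variance of all
#'   components), and `wavelengths` when fitted on a `spectra_set`.
#' @export
pca_fit <- function(x, n_pcs = 10L) {
  wl <- NULL
  if (inherits(x, "spectra_set")) {
    wl <- x$wavelengths
    x <- x$absorbance
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L)
    spst_error("PCA requires at least 2 samples", "sproutspec_config_error")
  n_pcs <- as.integer(n_pcs)
  max_pcs <- min(n - 1L, ncol(x))
  if (n_pcs > max_pcs)
    spst_error(sprintf("n_pcs = %d exceeds min(n_samples - 1, n_variables) = %d",
                       n_pcs, max_pcs), "sproutspec_config_error")
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sv <- svd(xc, nu = n_pcs, nv = n_pcs)
  total_var <- sum(sv$d^2)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  # sign convention: largest-|.| loading element positive
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- loadings[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1L))
  loadings <- sweep(loadings, 2L, flip, `*`)
  scores <- sweep(scores, 2L, flip, `*`)
  structure(list(center = center, loadings = loadings, scores = scores,
                 explained_var_pct = 100 * sv$d[seq_len(n_pcs)]^2 / total_var,
                 singular_values = sv$d, wavelengths = wl),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d PCs; explained variance: %s %%\n",
              ncol(x$loadings),
              paste(sprintf("%.2f", x$explained_var_pct), collapse = ", ")))
  invisible(x)
}

#' Project new spectra onto fitted principal components
#'
#' @param object A `pca_model`.
#' @param newdata A `spectra_set` or matrix on the same variable grid.
#' @param ... Unused.
#' @return Score matrix (samples x PCs).
#' @export
predict.pca_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$absorbance
  sweep(as.matrix(newdata), 2L, object$center) %*% object$loadings
}

#' Important wavelengths from PC loading extrema
#'
#' Scans the loading curve of each requested PC for local extrema whose
#' absolute loading reaches at least `prominence_frac` of that PC's maximum
#' absolute loading, then deduplicates the pooled candidates within
#' `min_separation_nm` (keeping the larger |loading|).
#'
#' @param model A `pca_model` fitted on a wavelength-indexed dataset.
#' @param pcs PCs to scan (default PC1 and PC2).
#' @param prominence_frac Minimum |loading| as a fraction of the PC maximum
#'   (default 0.5).
#' @param min_separation_nm Minimum spacing between reported wavelengths
#'   (default 10 nm).
#' @return Sorted numeric vector of wavelengths in nm (possibly empty, with
#'   a warning).
#' @export
select_important_wavelengths <- function(model, pcs = c(1L, 2L),
                                         prominence_frac = 0.5,
                                         min_separation_nm = 10) {
  if (is.null(model$wavelengths))
    spst_error("model was not fitted on a wavelength-indexed dataset",
               "sproutspec_config_error")
  wl <- model$wavelengths
  cand_nm <- numeric()
  cand_mag <- numeric()
  for (pc in pcs) {
    v <- model$loadings[, pc]
    ext <- local_extrema(v)
    keep <- abs(v[ext]) >= prominence_frac * max(abs(v))
    cand_nm <- c(cand_nm, wl[ext[keep]])
    cand_mag <- c(cand_mag, abs(v[ext[keep]]))
  }
  if (!length(cand_nm)) {
    warning("no loading extrema above the prominence threshold")
    return(numeric())
  }
  ord <- order(cand_mag, decreasing = TRUE)
  kept <- numeric()
  for (i in ord) {
    if (!length(kept) || all(abs(kept - cand_nm[i]) >= min_separation_nm))
      kept <- c(kept, cand_nm[i])
  }
  sort(kept)
}

# interior local extrema of a curve; plateaus report their first point.
# endpoints are never extrema (mirrors usual peak-finding conventions and
# avoids flagging truncation-window edges).
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  idx <- integer()
  for (i in 2:(n - 1L)) {
    up <- v[i] - v[i - 1L]
    dn <- v[i + 1L] - v[i]
    if ((up > 0 && dn <= 0) || (up < 0 && dn >= 0))
      idx <- c(idx, i)
  }
  idx
}
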