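#' Linear discriminant analysis on principal component scores
#'
#' Fits PCA to the spectra, then canonical discriminant axes ("roots") in
#' the space of the first `n_pcs` scores by eigen-decomposition of
#' `pooled_within^-1 %*% between` scatter. Axes are scaled so the pooled
#' within-class variance along each root is 1, which makes nearest-centroid
#' classification in root space equivalent to Mahalanobis LDA with equal
#' priors. An ill-conditioned pooled scatter receives a ridge of
#' `1e-8 * trace / dim` with a warning.
#'
#' @param x A [spectra_set()] or score-producing matrix.
#' @param labels Class label per sample (factor or coercible).
#' @param n_pcs Number of PC scores fed to the discriminant (default 10).
#' @return A `pca_lda_model` with the underlying `pca`, `class_labels`,
#'   `canonical_axes` (PC space x roots), `class_centroids` (root space),
#'   `root_eigenvalues` and `pooled_within_scatter`.
#' @export
pca_lda_fit <- function(x, labels, n_pcs = 10L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    spst_error("LDA requires at least 2 classes", "sproutspec_config_error")
  if (any(table(labels) < 2L))
    spst_error("every class needs at least 2 samples", "sproutspec_config_error")
  pca <- pca_fit(x, n_pcs = n_pcs)
  lda <- lda_on_scores(pca$scores, labels)
  structure(c(list(pca = pca, n_pcs = as.integer(n_pcs)), lda),
            class = "pca_lda_model")
}

# canonical discriminant computation in an already-projected score space
lda_on_scores <- function(scores, labels) {
  labels <- factor(labels)
  k <- nlevels(labels)
  p <- ncol(scores)
  n <- nrow(scores)
  gm <- colMeans(scores)
  centroids_x <- t(vapply(levels(labels), function(l) {
    colMeans(scores[labels == l, , drop = FALSE])
  }, numeric(p)))
  counts <- as.vector(table(labels))
  Sw <- matrix(0, p, p)
  for (i in seq_len(k)) {
    xi <- scores[labels == levels(labels)[i], , drop = FALSE]
    xi <- sweep(xi, 2L, centroids_x[i, ])
    Sw <- Sw + crossprod(xi)
  }
  Sw <- Sw / (n - k)
  if (rcond_safe(Sw) < 1e-10) {
    warning("pooled within-class scatter ill-conditioned; adding ridge")
    Sw <- Sw + diag(1e-8 * sum(diag(Sw)) / p, p)
  }
  Bd <- sweep(centroids_x, 2L, gm)
  Sb <- crossprod(Bd * sqrt(counts)) / n
  ei <- eigen(solve(Sw, Sb))
  n_roots <- min(k - 1L, p)
  A <- Re(ei$vectors[, seq_len(n_roots), drop = FALSE])
  evals <- Re(ei$values[seq_len(n_roots)])
  # scale each root to unit pooled within-class variance
  for (j in seq_len(n_roots)) {
    s <- sqrt(drop(crossprod(A[, j], Sw %*% A[, j])))
    A[, j] <- A[, j] / s
  }
  list(class_labels = levels(labels),
       canonical_axes = A,
       root_eigenvalues = evals,
       class_centroids = centroids_x %*% A,
       pooled_within_scatter = Sw,
       grand_mean = gm)
}

#' Classify spectra with a fitted PCA-LDA model
#'
#' New spectra are projected through the stored PCA, mapped to root space
#' and assigned to the nearest class centroid (Euclidean distance; ties
#' break to the lowest class label).
#'
#' @param object A `pca_lda_model`.
#' @param newdata A `spectra_set` or matrix.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.pca_lda_model <- function(object, newdata, ...) {
  scores <- predict(object$pca, newdata)
  roots <- scores %*% object$canonical_axes
  cent <- object$class_centroids
  d2 <- outer(rowSums(roots^2), rowSums(cent^2), `+`) -
    2 * roots %*% t(cent)
  object$class_labels[apply(d2, 1L, which.min)]
}

#' Project spectra to LDA root space
#' @param object A `pca_lda_model`.
#' @param newdata A `spectra_set` or matrix.
#' @return Matrix of root scores (samples x roots).
#' @export
lda_roots <- function(object, newdata) {
  predict(object$pca, newdata) %*% object$canonical_axes
}

#' Replicate- or group-fold cross-validated PCA-LDA classification
#'
#' For each fold, PCA and LDA are refit on the calibration rows only — the
#' validation rows never influence centring, loadings or scatter (no
#' leakage). Recognition accuracy is measured on the calibration rows,
#' prediction accuracy on the held-out rows; both are averaged over folds
#' and a pooled validation confusion matrix is returned.
#'
#' @param x A preprocessed [spectra_set()].
#' @param labels Class label per sample.
#' @param scheme A [cv_scheme()]; `"replicate_3fold"` reproduces the
#'   leave-one-replicate-out design (replicate metadata must be 1..3).
#' @param n_pcs PCs per calibration fold (default 10).
#' @return A list with `accuracy_recognition_pct`, `accuracy_prediction_pct`,
#'   `per_fold` data frame and `confusion` matrix (true x predicted).
#' @export
crossval_lda <- function(x, labels, scheme = cv_scheme("replicate_3fold"),
                         n_pcs = 10L) {
  labels <- factor(labels)
  folds <- make_folds(x, scheme)
  lv <- levels(labels)
  if (length(lv) == 1L) {
    # degenerate but well-defined: the only class is always predicted
    n <- n_spectra(x)
    return(list(accuracy_recognition_pct = 100,
                accuracy_prediction_pct = 100,
                per_fold = data.frame(fold = sort(unique(folds)),
                                      recognition_pct = 100,
                                      prediction_pct = 100),
                confusion = matrix(n, 1L, 1L, dimnames = list(lv, lv))))
  }
  confusion <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  rec <- pred <- numeric(length(unique(folds)))
  fold_ids <- sort(unique(folds))
  for (fi in seq_along(fold_ids)) {
    val <- folds == fold_ids[fi]
    cal_labels <- labels[!val]
    if (!all(lv %in% cal_labels))
      spst_error(sprintf("class '%s' absent from calibration in fold %s",
                         setdiff(lv, unique(as.character(cal_labels)))[1L],
                         fold_ids[fi]), "sproutspec_fold_design_error")
    model <- pca_lda_fit(subset_spectra(x, !val), cal_labels, n_pcs = n_pcs)
    rec[fi] <- 100 * mean(predict(model, subset_spectra(x, !val)) ==
                            as.character(cal_labels))
    pv <- predict(model, subset_spectra(x, val))
    truth <- as.character(labels[val])
    pred[fi] <- 100 * mean(pv == truth)
    for (i in seq_along(pv))
      confusion[truth[i], pv[i]] <- confusion[truth[i], pv[i]] + 1L
  }
  list(accuracy_recognition_pct = mean(rec),
       accuracy_prediction_pct = mean(pred),
       per_fold = data.frame(fold = fold_ids, recognition_pct = rec,
                             prediction_pct = pred),
       confusion = confusion)
}

rcond_safe <- function(m) {
  out <- tryCatch(rcond(m), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}
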