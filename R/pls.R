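#' Partial least squares regression (PLS1, NIPALS)
#'
#' Univariate-response PLS fitted by the NIPALS algorithm with X-deflation.
#' The regression vector is assembled as `W (P'W)^-1 q`, so prediction
#' through the vector is identical (to numerical precision) to prediction
#' through sequential latent-variable deflation.
#'
#' @param X A [spectra_set()] or predictor matrix (samples x variables),
#'   e.g. absorbance at selected wavelengths.
#' @param y Numeric response vector.
#' @param n_lv Number of latent variables.
#' @return A `plsr_model` with centres, `weights` (W), `x_loadings` (P),
#'   `y_loadings` (q), `regression_vector`, `fitted`, and calibration
#'   metrics `r2` / `rmsec`.
#' @export
plsr_fit <- function(X, y, n_lv) {
  wl <- NULL
  if (inherits(X, "spectra_set")) {
    wl <- X$wavelengths
    X <- X$absorbance
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    spst_error("X and y sizes differ", "sproutspec_config_error")
  if (stats::var(y) == 0)
    spst_error("response has zero variance", "sproutspec_degenerate_response")
  n_lv <- as.integer(n_lv)
  if (n_lv > min(nrow(X) - 1L, ncol(X)))
    spst_error("n_lv exceeds min(n_samples - 1, n_predictors)",
               "sproutspec_config_error")
  fit <- nipals_pls1(X, y, n_lv)
  yhat <- drop(sweep(X, 2L, fit$x_center) %*% fit$regression_vector) +
    fit$y_center
  m <- regression_metrics(y, yhat)
  structure(c(fit, list(wavelengths = wl, fitted = yhat,
                        r2 = m$r2, rmsec = m$rmse)),
            class = "plsr_model")
}

nipals_pls1 <- function(X, y, n_lv) {
  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2L, x_center)
  f <- y - y_center
  p_var <- ncol(X)
  W <- P <- matrix(0, p_var, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * 1e3) {
      # X exhausted: keep earlier components only
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]
      n_lv <- a - 1L
      break
    }
    w <- w / nw
    tt <- drop(E %*% w)
    t2 <- sum(tt^2)
    p <- drop(crossprod(E, tt)) / t2
    qa <- sum(f * tt) / t2
    E <- E - tcrossprod(tt, p)
    f <- f - qa * tt
    W[, a] <- w
    P[, a] <- p
    q[a] <- qa
  }
  b <- if (n_lv > 0L) {
    drop(W %*% solve(crossprod(P, W), q))
  } else rep(0, p_var)
  list(n_lv = n_lv, x_center = x_center, y_center = y_center,
       weights = W, x_loadings = P, y_loadings = q,
       regression_vector = b)
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d LV; R2 = %.4f, RMSEC = %.4f", x$n_lv, x$r2,
              x$rmsec))
  if (!is.null(x$r2_cv)) cat(sprintf(", R2CV = %.4f, RMSECV = %.4f",
                                     x$r2_cv, x$rmsecv))
  cat("\n")
  invisible(x)
}

#' Predict responses from a fitted PLSR model
#' @param object A `plsr_model`.
#' @param newdata A `spectra_set` or predictor matrix.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$absorbance
  drop(sweep(as.matrix(newdata), 2L, object$x_center) %*%
         object$regression_vector) + object$y_center
}

#' Grouped cross-validated PLSR with latent-variable selection
#'
#' For every candidate latent-variable count up to `max_lv` (silently
#' capped at the rank available in the smallest calibration fold), grouped
#' cross-validation computes RMSECV from held-out predictions; the chosen
#' count is the smallest whose RMSECV lies within 2 % of the global
#' minimum (a parsimony rule guarding against overfitting). The final
#' model is refit on all data at that count.
#'
#' @param X A [spectra_set()] or predictor matrix.
#' @param y Numeric response.
#' @param scheme A [cv_scheme()]; grouping metadata are taken from `X` when
#'   it is a `spectra_set`, otherwise supply `groups`.
#' @param max_lv Largest latent-variable count to consider (default 20).
#' @param groups Optional grouping vector when `X` is a bare matrix
#'   (germination time for `"group_kfold_by_time"`, replicate for
#'   `"replicate_3fold"`).
#' @return A `plsr_model` augmented with `r2_cv`, `rmsecv`, `cv_predictions`
#'   and the per-candidate `rmsecv_curve`.
#' @export
plsr_crossval <- function(X, y, scheme = cv_scheme("group_kfold_by_time"),
                          max_lv = 20L, groups = NULL) {
  Xm <- if (inherits(X, "spectra_set")) X$absorbance else as.matrix(X)
  y <- as.numeric(y)
  folds <- if (inherits(X, "spectra_set")) make_folds(X, scheme)
           else make_folds(groups, scheme)
  fold_ids <- sort(unique(folds))
  min_cal <- min(vapply(fold_ids, function(f) sum(folds != f), integer(1L)))
  cap <- min(as.integer(max_lv), min_cal - 1L, ncol(Xm))
  if (cap < as.integer(max_lv))
    message(sprintf("max_lv capped at %d by calibration fold size/rank", cap))
  cv_pred <- matrix(NA_real_, nrow(Xm), cap)
  for (f in fold_ids) {
    val <- folds == f
    fit <- nipals_pls1(Xm[!val, , drop = FALSE], y[!val], cap)
    Ev <- sweep(Xm[val, , drop = FALSE], 2L, fit$x_center)
    for (a in seq_len(cap)) {
      if (a > fit$n_lv) {
        cv_pred[val, a] <- cv_pred[val, fit$n_lv]
        next
      }
      Wa <- fit$weights[, seq_len(a), drop = FALSE]
      Pa <- fit$x_loadings[, seq_len(a), drop = FALSE]
      qa <- fit$y_loadings[seq_len(a)]
      b <- drop(Wa %*% solve(crossprod(Pa, Wa), qa))
      cv_pred[val, a] <- drop(Ev %*% b) + fit$y_center
    }
  }
  rmsecv_curve <- sqrt(colMeans((cv_pred - y)^2))
  best <- min(rmsecv_curve)
  n_lv <- which(rmsecv_curve <= 1.02 * best)[1L]
  model <- plsr_fit(X, y, n_lv)
  mcv <- regression_metrics(y, cv_pred[, n_lv])
  model$r2_cv <- mcv$r2
  model$rmsecv <- mcv$rmse
  model$cv_predictions <- cv_pred[, n_lv]
  model$rmsecv_curve <- rmsecv_curve
  model$folds <- folds
  model
}

#' Coefficient of determination and root mean square error
#'
#' `r2 = 1 - SSres / SStot` (SStot about the mean of `y_true`; can be
#' negative for models worse than the mean) and
#' `rmse = sqrt(mean((y_true - y_pred)^2))`.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @return List with `r2` and `rmse`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2L)
    spst_error("y_true and y_pred must have equal length >= 2",
               "sproutspec_config_error")
  sstot <- sum((y_true - mean(y_true))^2)
  if (sstot == 0)
    spst_error("R2 undefined for constant y_true", "sproutspec_degenerate_response")
  ssres <- sum((y_true - y_pred)^2)
  list(r2 = 1 - ssres / sstot, rmse = sqrt(mean((y_true - y_pred)^2)))
}
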