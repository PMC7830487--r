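#' Group summary records
#'
#' @param label Group labels.
#' @param mean Group means.
#' @param sd Sample standard deviations (>= 0).
#' @param n Group sizes (integer >= 2).
#' @return A `group_summary` data frame.
#' @export
group_summary <- function(label, mean, sd, n) {
  if (any(sd < 0) || any(n < 2L))
    spst_error("group summaries need sd >= 0 and n >= 2",
               "sproutspec_config_error")
  structure(data.frame(label = label, mean = mean, sd = sd, n = as.integer(n),
                       stringsAsFactors = FALSE),
            class = c("group_summary", "data.frame"))
}

#' One-way ANOVA from summary statistics
#'
#' Reconstructs the one-way ANOVA table from per-group (mean, sd, n):
#' `SSB = sum n_i (mean_i - grand_mean)^2`, `SSW = sum (n_i - 1) sd_i^2`,
#' `F = (SSB / (k - 1)) / (SSW / sum(n_i - 1))`, with the p-value from the
#' F distribution's upper tail. This is algebraically identical to raw-data
#' one-way ANOVA when the summaries were computed from the raw values.
#'
#' @param groups A [group_summary()] data frame (or anything with columns
#'   `mean`, `sd`, `n`).
#' @return List with `f_stat`, `df_between`, `df_within`, `p_value`,
#'   `ms_within`, `ss_between`, `ss_within`.
#' @export
anova_oneway_from_summary <- function(groups) {
  k <- nrow(groups)
  if (k < 2L)
    spst_error("ANOVA needs at least 2 groups", "sproutspec_config_error")
  n <- groups$n
  m <- groups$mean
  grand <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * groups$sd^2)
  df_b <- k - 1L
  df_w <- sum(n - 1L)
  if (ssw == 0) {
    if (ssb == 0)
      return(list(f_stat = 0, df_between = df_b, df_within = df_w,
                  p_value = 1, ms_within = 0, ss_between = 0, ss_within = 0))
    return(list(f_stat = Inf, df_between = df_b, df_within = df_w,
                p_value = 0, ms_within = 0, ss_between = ssb, ss_within = 0))
  }
  f <- (ssb / df_b) / (ssw / df_w)
  list(f_stat = f, df_between = df_b, df_within = df_w,
       p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       ms_within = ssw / df_w, ss_between = ssb, ss_within = ssw)
}

#' One-way ANOVA from raw values
#'
#' Convenience wrapper summarising raw observations per group and calling
#' [anova_oneway_from_summary()].
#'
#' @param values Numeric observations.
#' @param labels Group label per observation.
#' @return As [anova_oneway_from_summary()].
#' @export
anova_oneway <- function(values, labels) {
  labels <- factor(labels)
  gs <- group_summary(levels(labels),
                      tapply(values, labels, mean),
                      tapply(values, labels, stats::sd),
                      tapply(values, labels, length))
  anova_oneway_from_summary(gs)
}

#' Duncan's multiple range test with letter display
#'
#' Groups are ranked by mean; the least significant range for a span of
#' `p` ranked means is `R_p = q(1 - alpha_p, p, df_w) * sqrt(MSE / n)`
#' where `q` is the studentized-range quantile and Duncan's protection
#' level is `alpha_p = 1 - (1 - alpha)^(p - 1)`. Two means differ
#' significantly when their difference exceeds the range for their span
#' and no enclosing span was non-significant. Maximal non-significant runs
#' receive shared letters (a, b, ...), so groups sharing any letter are
#' pairwise non-significant under the test. Unequal group sizes use the
#' harmonic mean n with a warning.
#'
#' @param groups A [group_summary()] data frame.
#' @param alpha Significance level (default 0.05).
#' @return A `dmrt_result`: `groups` data frame (ranked, with `letters`),
#'   `critical_ranges` (named by span), `ms_within`, `df_within`, `alpha`.
#' @export
dmrt <- function(groups, alpha = 0.05) {
  an <- anova_oneway_from_summary(groups)
  k <- nrow(groups)
  n_use <- if (length(unique(groups$n)) > 1L) {
    warning("unequal group sizes: using harmonic mean n")
    k / sum(1 / groups$n)
  } else groups$n[1L]
  spans <- 2:k
  Rp <- vapply(spans, function(p) {
    stats::qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, an$df_within) *
      sqrt(an$ms_within / n_use)
  }, numeric(1L))
  names(Rp) <- spans
  ord <- order(groups$mean, decreasing = TRUE)
  m <- groups$mean[ord]
  # reach[i]: last ranked index still non-significant from i, forced
  # monotone so that an enclosing non-significant span protects sub-pairs
  reach <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && (m[i] - m[j + 1L]) <= Rp[as.character(j + 1L - i + 1L)])
      j <- j + 1L
    reach[i] <- j
  }
  # an enclosing non-significant span [h, reach[h]] protects every pair
  # inside it, so the effective reach is monotone
  reach <- cummax(reach)
  letters_out <- character(k)
  lab_i <- 0L
  prev_end <- 0L
  for (i in seq_len(k)) {
    if (reach[i] > prev_end || (i == 1L)) {
      lab_i <- lab_i + 1L
      span <- i:reach[i]
      letters_out[span] <- paste0(letters_out[span], letter_seq(lab_i))
      prev_end <- reach[i]
    }
  }
  res <- groups[ord, , drop = FALSE]
  res$rank <- seq_len(k)
  res$letters <- letters_out
  # ascending-mean letter order is the usual table convention: relabel so
  # the smallest mean gets "a"
  res <- res[order(res$mean), , drop = FALSE]
  uniq <- unique(unlist(strsplit(res$letters, "")))
  map <- stats::setNames(letter_seq(seq_along(uniq)), uniq)
  res$letters <- vapply(strsplit(res$letters, ""), function(ch)
    paste(sort(map[ch]), collapse = ""), character(1L))
  rownames(res) <- NULL
  structure(list(groups = res, critical_ranges = Rp,
                 ms_within = an$ms_within, df_within = an$df_within,
                 alpha = alpha),
            class = "dmrt_result")
}

letter_seq <- function(i) {
  # a, b, ..., z, aa, ab, ... for many groups
  vapply(i, function(j) {
    out <- ""
    j <- j - 1L
    repeat {
      out <- paste0(letters[j %% 26L + 1L], out)
      j <- j %/% 26L - 1L
      if (j < 0L) break
    }
    out
  }, character(1L))
}

#' @export
print.dmrt_result <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, df = %d)\n",
              x$alpha, x$df_within))
  print(x$groups[, c("label", "mean", "sd", "n", "letters")])
  invisible(x)
}

#' Durbin-Watson statistic
#'
#' `DW = sum((e_t - e_{t-1})^2) / sum(e_t^2)` on ordered residuals; values
#' near 2 indicate no first-order autocorrelation, near 0 positive and
#' near 4 negative autocorrelation.
#'
#' @param residuals Ordered numeric residuals, length >= 2, not all zero.
#' @return The statistic in \[0, 4\].
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2L)
    spst_error("need at least 2 residuals", "sproutspec_config_error")
  den <- sum(residuals^2)
  if (den == 0)
    spst_error("Durbin-Watson undefined for all-zero residuals",
               "sproutspec_degenerate_response")
  sum(diff(residuals)^2) / den
}

#' Durbin-Watson on residuals of a straight-line trend
#'
#' Fits `y ~ x` by least squares and returns the Durbin-Watson statistic
#' of the residuals in `x` order — the autocorrelation screen applied to
#' quality trends before plotting.
#'
#' @param x Ordering variable (e.g. germination time).
#' @param y Response.
#' @return The Durbin-Watson statistic.
#' @export
durbin_watson_trend <- function(x, y) {
  o <- order(x)
  fit <- stats::lm.fit(cbind(1, x[o]), y[o])
  durbin_watson(fit$residuals)
}
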