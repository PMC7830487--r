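#' Cross-validation scheme
#'
#' Two designs are supported. `"replicate_3fold"` leaves one measurement
#' replicate out at a time, so each of replicates 1-3 is validated exactly
#' once against a calibration set built from the other two.
#' `"group_kfold_by_time"` keeps all spectra sharing a germination time in
#' the same fold (leave-time-out): the distinct time points are shuffled
#' with the scheme's seed and dealt round-robin into `k` folds.
#'
#' @param kind `"replicate_3fold"` or `"group_kfold_by_time"`.
#' @param k Number of folds for the grouped k-fold design (default 6).
#' @param seed Integer seed for the fold shuffle (default 1).
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(kind = c("replicate_3fold", "group_kfold_by_time"),
                      k = 6L, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Fold assignment for a spectra set
#'
#' Every sample lands in exactly one validation fold; grouped designs keep
#' whole groups together.
#'
#' @param x A [spectra_set()] (metadata supply replicate / germination_h),
#'   or a vector of grouping values when `scheme$kind` needs one.
#' @param scheme A [cv_scheme()].
#' @return Integer fold id per sample.
#' @export
make_folds <- function(x, scheme) {
  meta <- if (inherits(x, "spectra_set")) x$meta else NULL
  if (scheme$kind == "replicate_3fold") {
    rep_v <- if (!is.null(meta)) meta$replicate else x
    if (is.null(rep_v) || !all(rep_v %in% 1:3))
      spst_error("replicate_3fold requires replicate metadata in {1,2,3}",
                 "sproutspec_fold_design_error")
    return(as.integer(rep_v))
  }
  grp <- if (!is.null(meta)) meta$germination_h else x
  if (is.null(grp) || anyNA(grp))
    spst_error("group_kfold_by_time requires germination_h metadata",
               "sproutspec_fold_design_error")
  ug <- sort(unique(grp))
  k <- min(scheme$k, length(ug))
  ord <- with_seed(scheme$seed, sample.int(length(ug)))
  fold_of_group <- integer(length(ug))
  fold_of_group[ord] <- rep_len(seq_len(k), length(ug))
  fold_of_group[match(grp, ug)]
}

# evaluate expr under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
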