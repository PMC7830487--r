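#' Export a fitted model as JSON
#'
#' Serialises PCA, PCA-LDA and PLSR models (centres, loadings, axes,
#' regression vectors, metrics) so the CLI `predict` subcommand can reuse
#' them without refitting.
#'
#' @param model A `pca_model`, `pca_lda_model` or `plsr_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_model_json <- function(model, path) {
  kind <- class(model)[1L]
  payload <- switch(kind,
    pca_model = model[c("center", "loadings", "explained_var_pct",
                        "wavelengths")],
    plsr_model = model[c("n_lv", "x_center", "y_center", "regression_vector",
                         "wavelengths", "r2", "rmsec", "r2_cv", "rmsecv")],
    pca_lda_model = list(
      pca = model$pca[c("center", "loadings", "wavelengths")],
      class_labels = model$class_labels,
      canonical_axes = model$canonical_axes,
      class_centroids = model$class_centroids),
    spst_error(sprintf("cannot serialise class '%s'", kind),
               "sproutspec_config_error"))
  jsonlite::write_json(list(kind = kind, payload = payload), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Import a model exported with [export_model_json()]
#'
#' @param path JSON path.
#' @return The model object; matrix-valued fields are restored.
#' @export
import_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$payload
  as_mat <- function(m) if (is.null(m)) NULL else as.matrix(m)
  model <- switch(obj$kind,
    pca_model = {
      p$loadings <- as_mat(p$loadings)
      p
    },
    plsr_model = {
      p$regression_vector <- as.numeric(p$regression_vector)
      p
    },
    pca_lda_model = {
      p$pca$loadings <- as_mat(p$pca$loadings)
      class(p$pca) <- "pca_model"
      p$canonical_axes <- as_mat(p$canonical_axes)
      p$class_centroids <- as_mat(p$class_centroids)
      p
    },
    spst_error(sprintf("unknown model kind '%s'", obj$kind),
               "sproutspec_format_error"))
  structure(model, class = obj$kind)
}
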