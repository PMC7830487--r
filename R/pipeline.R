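#' Run one analysis end-to-end from a configuration
#'
#' Executes preprocess then one of the study's analyses and writes a
#' reproducible report bundle into `out_dir`: fitted model (JSON), metrics
#' (CSV), confusion matrix / selected wavelengths / aquagram tables where
#' applicable, and a plain-text run log recording the package version,
#' seed, configuration hash and the exact preprocessing chain applied.
#' On failure, partial outputs are removed and the stage name is carried
#' in the error.
#'
#' @param config A named list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{input}{`list(csv = path)` or `list(simulate = "extract" |
#'       "standard_curve")`.}
#'     \item{preprocess}{Arguments for [preprocess_config()] (keys
#'       `sg_window`, `sg_polyorder`, `sg_derivative`, `snv`,
#'       `window_lo_nm`, `window_hi_nm`).}
#'     \item{analysis}{`"classify"`, `"predict"`, `"aquagram"` or
#'       `"standard_curve"`.}
#'     \item{target}{For `"predict"`: `"germination_h"`, `"water_pct"` or
#'       `"ascorbic"` (requires the simulated input's ground truth).}
#'     \item{cv}{Arguments for [cv_scheme()].}
#'     \item{selection}{Optional [select_important_wavelengths()]
#'       arguments (`pcs`, `prominence_frac`, `min_separation_nm`);
#'       `NULL` uses the full preprocessed grid.}
#'     \item{n_pcs, max_lv, seed, out_dir}{Scalars.}
#'   }
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the fitted objects and the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(out_dir))
    spst_error("config error: out_dir is required", "sproutspec_config_error")
  analysis <- config$analysis
  if (is.null(analysis) ||
      !analysis %in% c("classify", "predict", "aquagram", "standard_curve"))
    spst_error("config error: analysis must be one of classify/predict/aquagram/standard_curve",
               "sproutspec_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  note <- function(p) { written <<- c(written, p); p }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  loaded <- run_stage("input", load_pipeline_input(config, seed))
  pcfg <- do.call(preprocess_config, pipeline_preprocess_args(config))
  pre <- run_stage("preprocess", preprocess_pipeline(loaded$spectra, pcfg))
  result <- run_stage(analysis, switch(analysis,
    classify = pipeline_classify(pre, config, seed, out_dir, note),
    predict = pipeline_predict(pre, loaded$truth, config, seed, out_dir, note),
    standard_curve = pipeline_predict(pre, loaded$truth, config, seed,
                                      out_dir, note, standard_curve = TRUE),
    aquagram = pipeline_aquagram(pre, config, out_dir, note)))
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("sproutspec %s", as.character(utils::packageVersion("sproutspec"))),
    sprintf("date: %s", "run"),   # wall-clock excluded: logs must hash-match
    sprintf("seed: %d", seed),
    sprintf("analysis: %s", analysis),
    sprintf("preprocess: %s",
            paste(attr(pre, "preprocess_steps"), collapse = " -> ")),
    sprintf("config_hash: %s", config_hash(config))), log_path)
  note(log_path)
  invisible(c(result, list(paths = written, preprocessed = pre)))
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         null = "null")
  # rlang-free stable hash: sum of a rolling polynomial over the bytes
  b <- as.integer(charToRaw(as.character(js)))
  h <- 0
  for (x in b) h <- (h * 131 + x) %% 2147483647
  sprintf("%d", h)
}

pipeline_preprocess_args <- function(config) {
  p <- config$preprocess
  if (is.null(p)) p <- list()
  args <- list()
  if (!is.null(p$sg_window)) args$sg_window <- p$sg_window
  if (!is.null(p$sg_polyorder)) args$sg_polyorder <- p$sg_polyorder
  if (!is.null(p$sg_derivative)) args$sg_derivative <- p$sg_derivative
  if (!is.null(p$snv)) args$apply_snv <- p$snv
  args$window_lo_nm <- p$window_lo_nm
  args$window_hi_nm <- p$window_hi_nm
  args
}

load_pipeline_input <- function(config, seed) {
  inp <- config$input
  if (!is.null(inp$csv)) {
    return(list(spectra = read_spectra_csv(inp$csv), truth = NULL))
  }
  if (identical(inp$simulate, "extract")) {
    sim <- simulate_extract_spectra(spectra_sim_config(), seed = seed)
    return(sim)
  }
  if (identical(inp$simulate, "standard_curve")) {
    sp <- simulate_standard_curve(spectra_sim_config(), seed = seed)
    return(list(spectra = sp,
                truth = data.frame(analyte_conc = sp$meta$analyte_conc)))
  }
  spst_error("config error: input must name a csv or a simulate kind",
             "sproutspec_config_error")
}

pipeline_cv_scheme <- function(config, default_kind) {
  cvc <- config$cv
  if (is.null(cvc)) cvc <- list()
  cv_scheme(kind = if (is.null(cvc$kind)) default_kind else cvc$kind,
            k = if (is.null(cvc$k)) 6L else cvc$k,
            seed = if (is.null(cvc$seed)) 1L else cvc$seed)
}

pipeline_classify <- function(pre, config, seed, out_dir, note) {
  n_pcs <- if (is.null(config$n_pcs)) 10L else as.integer(config$n_pcs)
  scheme <- pipeline_cv_scheme(config, "replicate_3fold")
  cv <- crossval_lda(pre, pre$meta$germination_h, scheme, n_pcs = n_pcs)
  model <- pca_lda_fit(pre, pre$meta$germination_h, n_pcs = n_pcs)
  utils::write.csv(data.frame(metric = c("accuracy_recognition_pct",
                                         "accuracy_prediction_pct"),
                              value = c(cv$accuracy_recognition_pct,
                                        cv$accuracy_prediction_pct)),
                   note(file.path(out_dir, "metrics.csv")), row.names = FALSE)
  utils::write.csv(as.data.frame(cv$confusion),
                   note(file.path(out_dir, "confusion.csv")))
  export_model_json(model, note(file.path(out_dir, "model.json")))
  list(cv = cv, model = model)
}

pipeline_predict <- function(pre, truth, config, seed, out_dir, note,
                             standard_curve = FALSE) {
  target <- if (standard_curve) "analyte_conc"
            else if (is.null(config$target)) "water_pct" else config$target
  y <- switch(target,
    germination_h = pre$meta$germination_h,
    water_pct = truth$water_pct,
    ascorbic = truth$ascorbic_mg_100g,
    analyte_conc = pre$meta$analyte_conc,
    spst_error(sprintf("config error: unknown target '%s'", target),
               "sproutspec_config_error"))
  if (is.null(y))
    spst_error(sprintf("data error: no response available for target '%s'",
                       target), "sproutspec_data_error")
  sel <- config$selection
  X <- pre
  selected <- NULL
  if (!is.null(sel)) {
    pca <- pca_fit(pre, n_pcs = max(2L, length(sel$pcs %||% c(1L, 2L))))
    selected <- select_important_wavelengths(
      pca, pcs = sel$pcs %||% c(1L, 2L),
      prominence_frac = sel$prominence_frac %||% 0.5,
      min_separation_nm = sel$min_separation_nm %||% 10)
    idx <- vapply(selected, function(nm) which.min(abs(pre$wavelengths - nm)),
                  integer(1L))
    X <- spectra_set(pre$wavelengths[idx],
                     pre$absorbance[, idx, drop = FALSE], pre$meta)
    utils::write.csv(data.frame(wavelength_nm = selected),
                     note(file.path(out_dir, "selected_wavelengths.csv")),
                     row.names = FALSE)
  }
  scheme <- pipeline_cv_scheme(config, "group_kfold_by_time")
  max_lv <- if (is.null(config$max_lv)) 20L else as.integer(config$max_lv)
  model <- if (standard_curve) {
    # standard solutions carry no germination time: group folds by level
    plsr_crossval(X$absorbance, y, scheme, max_lv = max_lv,
                  groups = X$meta$analyte_conc)
  } else {
    plsr_crossval(X, y, scheme, max_lv = max_lv)
  }
  utils::write.csv(data.frame(metric = c("n_lv", "r2", "rmsec", "r2_cv",
                                         "rmsecv"),
                              value = c(model$n_lv, model$r2, model$rmsec,
                                        model$r2_cv, model$rmsecv)),
                   note(file.path(out_dir, "metrics.csv")), row.names = FALSE)
  export_model_json(model, note(file.path(out_dir, "model.json")))
  list(model = model, selected_wavelengths = selected, y = y)
}

pipeline_aquagram <- function(pre, config, out_dir, note) {
  group_key <- config$group_key %||% "germination_h"
  display <- config$display_nm
  aq <- compute_aquagram(pre, group_key = group_key,
                         display_nm = if (is.null(display)) NULL
                                      else as.numeric(display))
  write_aquagram_csv(aq, note(file.path(out_dir, "aquagram.csv")))
  write_aquagram_csv(aq, note(file.path(out_dir, "aquagram_long.csv")),
                     long = TRUE)
  list(aquagram = aq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
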