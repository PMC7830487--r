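#' Default water matrix coordinate (WAMAC) table
#'
#' The twelve characteristic wavelength ranges C1-C12 of the first O-H
#' overtone (1300-1600 nm) where specific water species absorb: free water
#' and water vapour at the short-wavelength end through increasingly
#' hydrogen-bonded water toward 1500+ nm. The nm ranges here follow the
#' aquaphotomics literature's conventional coordinates; they are
#' configuration, not measured fact, and can be replaced wholesale (e.g.
#' display wavelengths 1462/1477/1489/1513 for plotting parity with
#' published radar charts).
#'
#' @return A data frame with columns `id`, `lo_nm`, `hi_nm`, `display_nm`
#'   and `species`; ranges are ascending and non-overlapping.
#' @export
default_wamac_table <- function() {
  tab <- data.frame(
    id = paste0("C", 1:12),
    lo_nm = c(1336, 1360, 1370, 1380, 1398, 1421, 1432, 1448, 1458, 1472,
              1482, 1506),
    hi_nm = c(1348, 1366, 1376, 1388, 1418, 1430, 1444, 1456, 1468, 1480,
              1495, 1516),
    display_nm = c(1344, 1364, 1374, 1384, 1412, 1426, 1440, 1452, 1462,
                   1476, 1488, 1512),
    species = c("water vapour / asymmetric stretch", "water solvation shell OH-(H2O)1,2,4",
                "O-H stretch + superoxide", "water solvation shell OH-(H2O)1,4",
                "free water / trapped water", "water hydration shell H-OH bend",
                "water solvation shell OH-(H2O)4", "water solvation shell OH-(H2O)4,5",
                "water solvation shell OH-(H2O)4,5 (bound)",
                "water with 1 hydrogen bond", "water with 2 hydrogen bonds",
                "strongly bound water (3-4 hydrogen bonds)"),
    stringsAsFactors = FALSE)
  validate_wamac_table(tab)
  tab
}

validate_wamac_table <- function(tab) {
  stopifnot(all(tab$lo_nm < tab$hi_nm),
            all(tab$lo_nm >= 1300), all(tab$hi_nm <= 1600),
            all(tab$display_nm >= tab$lo_nm & tab$display_nm <= tab$hi_nm))
  if (nrow(tab) > 1L && any(tab$lo_nm[-1L] <= tab$hi_nm[-nrow(tab)]))
    spst_error("WAMAC ranges must be ascending and non-overlapping",
               "sproutspec_config_error")
  invisible(tab)
}

#' Classify a wavelength into a WAMAC coordinate
#'
#' @param nm Wavelength in nm.
#' @param table A WAMAC table (default [default_wamac_table()]).
#' @return The coordinate id (e.g. `"C8"`) or `NA_character_` when the
#'   wavelength falls outside all ranges.
#' @export
wamac_classify <- function(nm, table = default_wamac_table()) {
  hit <- which(table$lo_nm <= nm & nm <= table$hi_nm)
  if (length(hit)) table$id[hit[1L]] else NA_character_
}

#' Aquagram: group-averaged standardized absorbance at WAMAC wavelengths
#'
#' For each display wavelength (nearest grid point), absorbance is
#' standardized across all samples of the set,
#' `z = (A - mean(A)) / sd(A)` with the sample sd, and then averaged
#' within groups. This is the classical aquagram; no further radial
#' min-max scaling is applied. The n-weighted mean of the group values is
#' 0 per wavelength by construction, so balanced groups have zero column
#' sums.
#'
#' @param x A preprocessed [spectra_set()] covering the first-overtone
#'   window.
#' @param group_key Metadata column to group by (e.g. `"germination_h"` or
#'   `"analyte_conc"`).
#' @param table WAMAC table; display wavelengths may be overridden via
#'   `display_nm`.
#' @param display_nm Optional numeric vector replacing the table's display
#'   wavelengths.
#' @return An `aquagram` object: `values` (groups x display wavelengths),
#'   `groups`, `display_nm`, `n_per_group`.
#' @export
compute_aquagram <- function(x, group_key = "germination_h",
                             table = default_wamac_table(),
                             display_nm = NULL) {
  if (n_spectra(x) < 2L)
    spst_error("aquagram needs at least 2 samples", "sproutspec_config_error")
  g <- x$meta[[group_key]]
  if (is.null(g))
    spst_error(sprintf("metadata column '%s' not found", group_key),
               "sproutspec_config_error")
  if (is.null(display_nm)) display_nm <- table$display_nm
  idx <- vapply(display_nm, function(nm) which.min(abs(x$wavelengths - nm)),
                integer(1L))
  A <- x$absorbance[, idx, drop = FALSE]
  mu <- colMeans(A)
  sdv <- apply(A, 2L, stats::sd)
  if (any(sdv == 0))
    spst_error(sprintf("degenerate band: zero variance at %.6g nm",
                       display_nm[which(sdv == 0)[1L]]),
               "sproutspec_degenerate_band")
  z <- sweep(sweep(A, 2L, mu), 2L, sdv, `/`)
  glev <- if (is.numeric(g)) sort(unique(g)) else unique(sort(as.character(g)))
  gf <- factor(g, levels = glev)
  counts <- tabulate(gf, nbins = length(glev))
  vals <- rowsum(z, gf) / counts
  dimnames(vals) <- list(as.character(glev), formatC(display_nm, format = "g"))
  structure(list(values = vals, groups = glev, display_nm = display_nm,
                 n_per_group = counts),
            class = "aquagram")
}

#' @export
print.aquagram <- function(x, ...) {
  cat(sprintf("<aquagram> %d groups x %d water bands\n", nrow(x$values),
              ncol(x$values)))
  print(round(x$values, 3))
  invisible(x)
}

#' Write an aquagram as CSV
#'
#' @param x An `aquagram`.
#' @param path Output path.
#' @param long If `TRUE`, writes radar-chart-ready long format
#'   (`group, nm, value`); otherwise a wide matrix with groups as rows.
#' @return `path`, invisibly.
#' @export
write_aquagram_csv <- function(x, path, long = FALSE) {
  if (long) {
    df <- data.frame(group = rep(rownames(x$values), ncol(x$values)),
                     nm = rep(x$display_nm, each = nrow(x$values)),
                     value = as.vector(x$values))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(group = rownames(x$values), x$values,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
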