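#' Configuration of the synthetic extract-spectra generator
#'
#' The generator emulates the germination study's acquisition design: 21
#' germination-time classes (0-120 h in 6 h steps) scanned in triplicate
#' with five consecutive scans each (15 spectra per class) on a 900-1700 nm
#' grid at 2 nm. Spectra are sums of Gaussian water bands in wavelength
#' whose amplitudes drift linearly with germination time — the free-water
#' band near 1412 nm loses amplitude while the strongly hydrogen-bonded
#' band near 1512 nm gains it — plus Beer-Lambert analyte bands near
#' 1414/1477/1503 nm whose height is linear in ascorbic acid
#' concentration, a multiplicative scatter factor, an additive baseline
#' offset and white noise. The ascorbic trajectory interpolates the
#' reference titration means ([sprout_ascorbic_reference()]) over the
#' 6 h class grid; extract concentration in mg/L assumes the 100 g beans /
#' 200 mL water recipe (factor 5 on mg per 100 g). Band widths and
#' amplitudes are simulation tuning constants, not measured facts.
#'
#' @param grid_lo_nm,grid_hi_nm,grid_step_nm Wavelength grid (default
#'   900-1700 nm at 2 nm, 401 points).
#' @param classes_h Germination time classes in hours.
#' @param n_replicates,n_scans Replicates per class and scans per
#'   replicate.
#' @param water_bands Data frame `name, center_nm, width_nm, amplitude,
#'   slope_per_h`: Gaussian peak height is `amplitude + slope_per_h * t`.
#' @param background_bands Fixed Gaussian bands outside the first overtone
#'   (second-overtone water region) giving the spectra a realistic
#'   envelope below 1300 nm; they carry no class information.
#' @param analyte_centers_nm,analyte_width_nm Analyte band positions and
#'   common width.
#' @param analyte_response_au_per_mg_l Peak absorbance added per mg/L of
#'   analyte at each analyte band.
#' @param extract_mg_l_per_mg_100g Dilution factor from mg/100 g beans to
#'   mg/L of extract (default 5 = 100 g / 0.2 L).
#' @param scatter_cv Coefficient of variation of the per-spectrum
#'   multiplicative lognormal scatter factor.
#' @param baseline_sd_au Sd of the per-spectrum additive offset (AU).
#' @param noise_sd_au Sd of iid per-point noise (AU).
#' @param seed Default RNG seed.
#' @return A `spectra_sim_config` list.
#' @export
spectra_sim_config <- function(grid_lo_nm = 900, grid_hi_nm = 1700,
                               grid_step_nm = 2,
                               classes_h = seq(0, 120, by = 6),
                               n_replicates = 3L, n_scans = 5L,
                               water_bands = default_water_bands(),
                               background_bands = default_background_bands(),
                               analyte_centers_nm = c(1414, 1477, 1503),
                               analyte_width_nm = 10,
                               analyte_response_au_per_mg_l = 2e-4,
                               extract_mg_l_per_mg_100g = 5,
                               scatter_cv = 0.01,
                               baseline_sd_au = 0.005,
                               noise_sd_au = 0.002,
                               seed = 1L) {
  cfg <- structure(as.list(environment()), class = "spectra_sim_config")
  t_rng <- range(cfg$classes_h)
  amp_lo <- cfg$water_bands$amplitude + cfg$water_bands$slope_per_h * t_rng[1L]
  amp_hi <- cfg$water_bands$amplitude + cfg$water_bands$slope_per_h * t_rng[2L]
  bad <- pmin(amp_lo, amp_hi) < 0
  if (any(bad))
    spst_error(sprintf("band '%s' has negative amplitude within the time range",
                       cfg$water_bands$name[bad][1L]), "sproutspec_config_error")
  out_of_grid <- cfg$water_bands$center_nm < grid_lo_nm |
    cfg$water_bands$center_nm > grid_hi_nm
  if (any(out_of_grid))
    spst_error("water band centre outside the wavelength grid",
               "sproutspec_config_error")
  cfg
}

#' @rdname spectra_sim_config
#' @export
default_water_bands <- function() {
  data.frame(name = c("overtone_shoulder", "free_water", "solvation",
                      "bound_water"),
             center_nm = c(1380, 1412, 1452, 1512),
             width_nm = c(12, 18, 14, 16),
             amplitude = c(0.25, 0.60, 0.45, 0.30),
             slope_per_h = c(-0.0004, -0.0012, 0.0004, 0.0018),
             stringsAsFactors = FALSE)
}

#' @rdname spectra_sim_config
#' @export
default_background_bands <- function() {
  data.frame(name = c("second_overtone", "combination_shoulder"),
             center_nm = c(970, 1190),
             width_nm = c(40, 35),
             amplitude = c(0.15, 0.08),
             slope_per_h = c(0, 0),
             stringsAsFactors = FALSE)
}

gaussian_band <- function(wl, center, width) exp(-(wl - center)^2 / (2 * width^2))

# deterministic noiseless signal for one class
extract_signal <- function(cfg, wl, t_h, conc_mg_l) {
  sig <- numeric(length(wl))
  wb <- rbind(cfg$water_bands, cfg$background_bands)
  for (i in seq_len(nrow(wb))) {
    amp <- wb$amplitude[i] + wb$slope_per_h[i] * t_h
    sig <- sig + amp * gaussian_band(wl, wb$center_nm[i], wb$width_nm[i])
  }
  if (conc_mg_l > 0) {
    for (cc in cfg$analyte_centers_nm)
      sig <- sig + conc_mg_l * cfg$analyte_response_au_per_mg_l *
        gaussian_band(wl, cc, cfg$analyte_width_nm)
  }
  sig
}

#' Simulate the extract spectra dataset
#'
#' Generates the full 21-class x 3-replicate x 5-scan design (315 spectra
#' at defaults) together with a per-spectrum ground-truth table: the water
#' content trajectory (reference means with per-replicate gravimetric
#' noise) and the ascorbic acid trajectory (interpolated reference
#' titration means, in mg/100 g and mg/L of extract). Output is
#' deterministic for a fixed seed; the caller's RNG stream is untouched.
#'
#' @param cfg A [spectra_sim_config()].
#' @param seed Seed overriding `cfg$seed`.
#' @return List with `spectra` (a [spectra_set()]) and `truth` (data frame
#'   with `sample_id`, `germination_h`, `replicate`, `scan`, `water_pct`,
#'   `ascorbic_mg_100g`, `ascorbic_mg_l`).
#' @export
simulate_extract_spectra <- function(cfg = spectra_sim_config(),
                                     seed = cfg$seed) {
  wl <- seq(cfg$grid_lo_nm, cfg$grid_hi_nm, by = cfg$grid_step_nm)
  qual <- sprout_quality_reference()
  asc <- sprout_ascorbic_reference()
  asc_traj <- stats::approx(asc$germination_h, asc$titration_mean,
                            xout = cfg$classes_h, rule = 2)$y
  water_mean <- stats::approx(qual$germination_h, qual$water_pct_mean,
                              xout = cfg$classes_h, rule = 2)$y
  water_sd <- stats::approx(qual$germination_h, qual$water_pct_sd,
                            xout = cfg$classes_h, rule = 2)$y
  sdlog <- sqrt(log1p(cfg$scatter_cv^2))
  n_row <- length(cfg$classes_h) * cfg$n_replicates * cfg$n_scans
  ab <- matrix(0, n_row, length(wl))
  meta <- vector("list", n_row)
  truth <- vector("list", n_row)
  with_seed(as.integer(seed), {
    r <- 0L
    for (ci in seq_along(cfg$classes_h)) {
      t_h <- cfg$classes_h[ci]
      conc <- asc_traj[ci] * cfg$extract_mg_l_per_mg_100g
      sig <- extract_signal(cfg, wl, t_h, conc)
      for (rep_i in seq_len(cfg$n_replicates)) {
        wtr <- water_mean[ci] + stats::rnorm(1L, 0, water_sd[ci])
        for (scan_i in seq_len(cfg$n_scans)) {
          r <- r + 1L
          scatter <- exp(stats::rnorm(1L, 0, sdlog))
          offset <- stats::rnorm(1L, 0, cfg$baseline_sd_au)
          ab[r, ] <- scatter * sig + offset +
            stats::rnorm(length(wl), 0, cfg$noise_sd_au)
          meta[[r]] <- data.frame(sample_id = sprintf("ext_t%03d", t_h),
                                  germination_h = t_h, replicate = rep_i,
                                  scan = scan_i, mode = "transmission",
                                  stringsAsFactors = FALSE)
          truth[[r]] <- data.frame(sample_id = sprintf("ext_t%03d", t_h),
                                   germination_h = t_h, replicate = rep_i,
                                   scan = scan_i, water_pct = wtr,
                                   ascorbic_mg_100g = asc_traj[ci],
                                   ascorbic_mg_l = conc)
        }
      }
    }
  })
  list(spectra = spectra_set(wl, ab, do.call(rbind, meta)),
       truth = do.call(rbind, truth))
}

#' Simulate the ascorbic acid standard-curve spectra
#'
#' Six concentration levels (0-500 mg/L in 100 mg/L steps), scanned in
#' triplicate with three consecutive scans each (54 spectra). Water bands
#' are held at their base amplitudes (no germination-time drift); the
#' analyte response is linear in concentration.
#'
#' @param cfg A [spectra_sim_config()] (its band/noise settings are
#'   reused).
#' @param concentrations_mg_l Concentration levels.
#' @param n_replicates,n_scans Replicates and scans per level (default
#'   3 x 3).
#' @param seed Seed overriding `cfg$seed`.
#' @return A [spectra_set()] with `analyte_conc` metadata.
#' @export
simulate_standard_curve <- function(cfg = spectra_sim_config(),
                                    concentrations_mg_l = seq(0, 500, by = 100),
                                    n_replicates = 3L, n_scans = 3L,
                                    seed = cfg$seed) {
  wl <- seq(cfg$grid_lo_nm, cfg$grid_hi_nm, by = cfg$grid_step_nm)
  sdlog <- sqrt(log1p(cfg$scatter_cv^2))
  n_row <- length(concentrations_mg_l) * n_replicates * n_scans
  ab <- matrix(0, n_row, length(wl))
  meta <- vector("list", n_row)
  with_seed(as.integer(seed), {
    r <- 0L
    for (conc in concentrations_mg_l) {
      sig <- extract_signal(cfg, wl, t_h = 0, conc_mg_l = conc)
      # standard solutions: water matrix fixed at t = 0 amplitudes
      for (rep_i in seq_len(n_replicates)) {
        for (scan_i in seq_len(n_scans)) {
          r <- r + 1L
          scatter <- exp(stats::rnorm(1L, 0, sdlog))
          offset <- stats::rnorm(1L, 0, cfg$baseline_sd_au)
          ab[r, ] <- scatter * sig + offset +
            stats::rnorm(length(wl), 0, cfg$noise_sd_au)
          meta[[r]] <- data.frame(sample_id = sprintf("std_c%03d", conc),
                                  germination_h = NA_integer_,
                                  replicate = rep_i, scan = scan_i,
                                  mode = "transmission",
                                  analyte_conc = conc,
                                  stringsAsFactors = FALSE)
        }
      }
    }
  })
  spectra_set(wl, ab, do.call(rbind, meta))
}

#' Simulate raw quality-parameter triplicates
#'
#' Draws `n` normal values per germination time for water content, pH,
#' conductivity and (at 24 h steps) titrated ascorbic acid, anchored to
#' the reference summary tables. With `sd_scale = 0` the draws collapse to
#' the printed means.
#'
#' @param seed RNG seed.
#' @param n Replicates per cell (default 3).
#' @param sd_scale Multiplier on the reference sds (default 1).
#' @return Long data frame `variable, germination_h, replicate, value`.
#' @export
simulate_quality_table <- function(seed = 1L, n = 3L, sd_scale = 1) {
  qual <- sprout_quality_reference()
  asc <- sprout_ascorbic_reference()
  cells <- rbind(
    data.frame(variable = "water_pct", germination_h = qual$germination_h,
               mean = qual$water_pct_mean, sd = qual$water_pct_sd),
    data.frame(variable = "ph", germination_h = qual$germination_h,
               mean = qual$ph_mean, sd = qual$ph_sd),
    data.frame(variable = "conductivity", germination_h = qual$germination_h,
               mean = qual$conductivity_mean, sd = qual$conductivity_sd),
    data.frame(variable = "ascorbic_titration",
               germination_h = asc$germination_h,
               mean = asc$titration_mean, sd = asc$titration_sd))
  with_seed(as.integer(seed), {
    out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      data.frame(variable = cells$variable[i],
                 germination_h = cells$germination_h[i],
                 replicate = seq_len(n),
                 value = stats::rnorm(n, cells$mean[i],
                                      sd_scale * cells$sd[i]),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
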