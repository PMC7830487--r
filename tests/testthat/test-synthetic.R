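test_that("generators are deterministic under a fixed seed", {
  a <- simulate_extract_spectra(seed = 7)
  b <- simulate_extract_spectra(seed = 7)
  expect_identical(a$spectra$absorbance, b$spectra$absorbance)
  expect_identical(a$truth, b$truth)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(a$spectra, fa)
  write_spectra_csv(b$spectra, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
  expect_false(identical(simulate_extract_spectra(seed = 8)$spectra$absorbance,
                         a$spectra$absorbance))
  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_extract_spectra(seed = 7))
  expect_identical(rnorm(3), before)
})

test_that("degenerate settings collapse to identical spectra", {
  wb <- default_water_bands()
  wb$slope_per_h <- 0
  cfg <- spectra_sim_config(water_bands = wb, scatter_cv = 0,
                            baseline_sd_au = 0, noise_sd_au = 0,
                            analyte_response_au_per_mg_l = 0)
  sim <- simulate_extract_spectra(cfg, seed = 1)
  expect_lt(max(abs(sweep(sim$spectra$absorbance, 2,
                          sim$spectra$absorbance[1, ]))), 1e-12)
})

test_that("negative band amplitudes over the time range are rejected", {
  wb <- default_water_bands()
  wb$slope_per_h[wb$name == "free_water"] <- -0.01   # negative by 120 h
  expect_error(spectra_sim_config(water_bands = wb), "free_water",
               class = "sproutspec_config_error")
})

test_that("water-band trends are monotone in class means", {
  # strict monotonicity holds by construction for the noiseless signal
  cfg0 <- spectra_sim_config(scatter_cv = 0, baseline_sd_au = 0,
                             noise_sd_au = 0)
  clean <- simulate_extract_spectra(cfg0, seed = 1)
  wl <- clean$spectra$wavelengths
  cls <- clean$spectra$meta$germination_h
  o <- order(as.numeric(names(tapply(cls, cls, length))))
  cm <- function(x, nm) tapply(x$spectra$absorbance[, which(wl == nm)],
                               x$spectra$meta$germination_h, mean)[o]
  expect_true(all(diff(cm(clean, 1512)) > 0))
  expect_true(all(diff(cm(clean, 1412)) < 0))
  # under the default noise the trend survives as a near-perfect rank
  # correlation of class means with time
  sim <- sim_extract_cached(1L)
  t21 <- seq(0, 120, by = 6)
  expect_gt(cor(cm(sim, 1512), t21, method = "spearman"), 0.99)
  expect_lt(cor(cm(sim, 1412), t21, method = "spearman"), -0.99)
})

test_that("standard-curve design and concentration response are as stated", {
  sp <- simulate_standard_curve(seed = 1)
  expect_equal(dim(sp), c(54L, 401L))
  expect_equal(sort(unique(sp$meta$analyte_conc)), seq(0, 500, by = 100))
  expect_equal(unname(table(sp$meta$analyte_conc))[1L], 9L,
               ignore_attr = TRUE)
  # absorbance at 1477 nm is affine in concentration
  a1477 <- sp$absorbance[, which(sp$wavelengths == 1476)]
  fit <- summary(lm(a1477 ~ sp$meta$analyte_conc))
  expect_gt(fit$coefficients[2, 1], 0)
  expect_lt(fit$coefficients[2, 4], 1e-6)
  # zero-concentration spectra carry water + noise only: their mean must
  # match the t = 0 extract water signal away from analyte bands
  cfg <- spectra_sim_config(noise_sd_au = 0, scatter_cv = 0,
                            baseline_sd_au = 0,
                            analyte_response_au_per_mg_l = 0)
  clean <- simulate_standard_curve(cfg, seed = 1)
  expect_lt(max(abs(clean$absorbance[1, ] - clean$absorbance[54, ])), 1e-12)
})

test_that("quality table draws are anchored to the reference summaries", {
  exact <- simulate_quality_table(seed = 1, sd_scale = 0)
  q <- sprout_quality_reference()
  w <- exact[exact$variable == "water_pct", ]
  expect_equal(unique(w$value[w$germination_h == 0]), 47.94)
  expect_equal(nrow(w), 21L * 3L)

  drawn <- simulate_quality_table(seed = 2)
  wm <- tapply(drawn$value[drawn$variable == "water_pct"],
               drawn$germination_h[drawn$variable == "water_pct"], mean)
  # |sample mean - anchor| < 2 sd / sqrt(3) for most cells
  dev <- abs(wm[as.character(q$germination_h)] - q$water_pct_mean)
  expect_gt(mean(dev < 2 * q$water_pct_sd / sqrt(3)), 0.8)
  # ANOVA on the generated water column is significant
  wdf <- drawn[drawn$variable == "water_pct", ]
  expect_lt(anova_oneway(wdf$value, wdf$germination_h)$p_value, 0.05)
})

test_that("class separability is monotone in the configured slopes", {
  acc_at <- function(scale, seed) {
    wb <- default_water_bands()
    wb$slope_per_h <- wb$slope_per_h * scale
    cfg <- spectra_sim_config(water_bands = wb, seed = seed)
    sim <- simulate_extract_spectra(cfg, seed = seed)
    pre <- preprocess_pipeline(sim$spectra, first_overtone_cfg())
    crossval_lda(pre, pre$meta$germination_h,
                 cv_scheme("replicate_3fold"))$accuracy_prediction_pct
  }
  # scaled down from the full 3 x 20-seed sweep: 3 levels x 5 seeds
  seeds <- 11:15
  acc <- vapply(c(0.1, 0.3, 1), function(s)
    mean(vapply(seeds, function(sd) acc_at(s, sd), numeric(1))), numeric(1))
  expect_true(all(diff(acc) >= 0))
})
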