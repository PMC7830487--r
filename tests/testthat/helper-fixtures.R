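# fixtures are built in code; nothing binary is shipped

# minimal rectangular set on an arbitrary grid
toy_spectra <- function(absorbance, wavelengths = NULL, ...) {
  absorbance <- as.matrix(absorbance)
  if (is.null(wavelengths))
    wavelengths <- seq(1300, by = 2, length.out = ncol(absorbance))
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(nrow(absorbance))),
                     ...)
  spectra_set(wavelengths, absorbance, meta)
}

# spectra whose rows are polynomials of lambda, for SG exactness checks
poly_spectra <- function(coefs, n_wl = 41L) {
  wl <- seq(1300, by = 2, length.out = n_wl)
  ab <- t(vapply(seq_len(nrow(coefs)), function(i) {
    drop(outer(wl - mean(wl), seq_len(ncol(coefs)) - 1L, `^`) %*% coefs[i, ])
  }, numeric(n_wl)))
  toy_spectra(ab, wl)
}

# default-config extract simulation, cached per seed within a test run
sim_extract_cached <- local({
  cache <- list()
  function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- simulate_extract_spectra(seed = seed)
    cache[[key]]
  }
})

first_overtone_cfg <- function(...)
  preprocess_config(window_lo_nm = 1300, window_hi_nm = 1600, ...)

# reference summary tables as group_summary objects
quality_groups <- function(column = "water_pct") {
  q <- sprout_quality_reference()
  group_summary(q$germination_h, q[[paste0(column, "_mean")]],
                q[[paste0(column, "_sd")]], q$n)
}

ascorbic_groups <- function() {
  a <- sprout_ascorbic_reference()
  group_summary(a$germination_h, a$titration_mean, a$titration_sd, a$n)
}
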