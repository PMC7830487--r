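test_that("WAMAC table is well formed and classifies anchor bands", {
  tab <- default_wamac_table()
  expect_equal(nrow(tab), 12L)
  expect_equal(tab$display_nm,
               c(1344, 1364, 1374, 1384, 1412, 1426, 1440, 1452, 1462, 1476,
                 1488, 1512))
  expect_true(all(tab$lo_nm >= 1300 & tab$hi_nm <= 1600))
  expect_true(all(diff(tab$lo_nm) > 0))
  expect_equal(wamac_classify(1381), "C4")
  expect_equal(wamac_classify(1454), "C8")
  expect_true(is.na(wamac_classify(1200)))
})

test_that("aquagram standardization follows the closed form", {
  # two equal-size groups differing by +delta at the 1512 band only
  delta <- 0.4
  n <- 6L
  wl <- default_wamac_table()$display_nm
  base <- matrix(rep(seq(0.2, by = 0.01, length.out = length(wl)), 2 * n),
                 2 * n, byrow = TRUE)
  base <- base + matrix(rnorm(2 * n * length(wl), sd = 1e-3), 2 * n)
  i1512 <- which(wl == 1512)
  base[(n + 1):(2 * n), i1512] <- base[(n + 1):(2 * n), i1512] + delta
  xs <- spectra_set(wl, base,
                    data.frame(sample_id = "x",
                               germination_h = rep(c(0L, 24L), each = n)))
  aq <- compute_aquagram(xs, "germination_h")
  # closed-form oracle: direct per-column standardization and group means
  z <- scale(base[, i1512])
  expect_equal(unname(aq$values[, i1512]),
               c(mean(z[1:n]), mean(z[(n + 1):(2 * n)])), tolerance = 1e-10)
  expect_equal(aq$values["0", i1512], -aq$values["24", i1512],
               tolerance = 1e-6, ignore_attr = TRUE)
  # other bands near zero
  expect_lt(max(abs(aq$values[, -i1512])), 1)
  # balanced groups: column sums zero
  expect_equal(unname(colSums(aq$values)), rep(0, length(wl)),
               tolerance = 1e-10)
})

test_that("aquagram weighted mean is zero and ordering is natural", {
  sim <- sim_extract_cached(1L)
  pre <- preprocess_pipeline(sim$spectra, first_overtone_cfg())
  aq <- compute_aquagram(pre, "germination_h")
  wmean <- colSums(aq$values * aq$n_per_group) / sum(aq$n_per_group)
  expect_equal(unname(wmean), rep(0, 12), tolerance = 1e-10)
  expect_equal(aq$groups, seq(0, 120, by = 6))
  # bound-water coordinate rises with germination time
  sub24 <- subset_spectra(pre, pre$meta$germination_h %% 24 == 0)
  aq24 <- compute_aquagram(sub24, "germination_h")
  v1512 <- aq24$values[, "1512"]
  expect_true(all(diff(v1512) > 0))
  # free-water display band falls
  expect_true(all(diff(aq24$values[, "1412"]) < 0))
})

test_that("aquagram is invariant to pre-SNV offsets and display override works", {
  sim <- sim_extract_cached(1L)
  shifted <- spectra_set(sim$spectra$wavelengths,
                         sim$spectra$absorbance + 0.37, sim$spectra$meta)
  a1 <- compute_aquagram(preprocess_pipeline(sim$spectra,
                                             first_overtone_cfg()),
                         "germination_h")
  a2 <- compute_aquagram(preprocess_pipeline(shifted, first_overtone_cfg()),
                         "germination_h")
  expect_equal(a1$values, a2$values, tolerance = 1e-8)
  a3 <- compute_aquagram(preprocess_pipeline(sim$spectra,
                                             first_overtone_cfg()),
                         "germination_h",
                         display_nm = c(1462, 1477, 1489, 1513))
  expect_equal(colnames(a3$values), c("1462", "1477", "1489", "1513"))
})

test_that("degenerate bands and identical spectra are rejected/zero", {
  wl <- default_wamac_table()$display_nm
  same <- matrix(1:12, 4, 12, byrow = TRUE)
  xs <- spectra_set(wl, same, data.frame(sample_id = "x",
                                         germination_h = c(0L, 0L, 24L, 24L)))
  expect_error(compute_aquagram(xs, "germination_h"),
               class = "sproutspec_degenerate_band")
  jit <- same + matrix(rnorm(48, sd = 1e-6), 4)
  aq <- compute_aquagram(spectra_set(wl, jit, xs$meta), "germination_h")
  expect_true(all(is.finite(aq$values)))
})

test_that("aquagram CSV writers emit wide and long forms", {
  wl <- default_wamac_table()$display_nm
  jit <- matrix(rnorm(4 * 12), 4)
  xs <- spectra_set(wl, jit, data.frame(sample_id = "x",
                                        germination_h = c(0L, 0L, 24L, 24L)))
  aq <- compute_aquagram(xs, "germination_h")
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  write_aquagram_csv(aq, wide)
  write_aquagram_csv(aq, long, long = TRUE)
  dfw <- read.csv(wide, check.names = FALSE)
  dfl <- read.csv(long)
  expect_equal(dim(dfw), c(2L, 13L))
  expect_equal(nrow(dfl), 24L)
  expect_equal(sort(unique(dfl$nm)), sort(wl))
})
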