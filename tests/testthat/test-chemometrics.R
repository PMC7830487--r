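test_that("PCA matches rank-1 geometry and the eigen oracle", {
  set.seed(1)
  tt <- rnorm(50)
  x <- cbind(tt, tt) + matrix(rnorm(100, sd = 1e-6), 50)
  p <- pca_fit(x, 2)
  expect_equal(abs(p$loadings[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-4)
  expect_gt(p$explained_var_pct[1], 99.99)

  # 4x3 integer toy: singular values squared match a direct eigen oracle
  m <- matrix(c(1, 4, 2, 8, 3, 1, 5, 7, 2, 9, 6, 3), 4, 3)
  p2 <- pca_fit(m, 3)
  oracle <- eigen(cov(m), symmetric = TRUE)$values
  expect_equal(p2$singular_values^2 / (nrow(m) - 1), oracle,
               tolerance = 1e-10)
  # loadings orthonormal, scores column-centred, full reconstruction
  expect_equal(crossprod(p2$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(colMeans(p2$scores), rep(0, 3), tolerance = 1e-10)
  expect_equal(p2$scores %*% t(p2$loadings),
               sweep(m, 2, colMeans(m)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_fit(m, 4), class = "sproutspec_config_error")
})

test_that("PC1 orders the synthetic extract by germination time", {
  sim <- sim_extract_cached(1L)
  pre <- preprocess_pipeline(sim$spectra, first_overtone_cfg())
  p <- pca_fit(pre, 2)
  expect_gt(abs(cor(p$scores[, 1], pre$meta$germination_h,
                    method = "spearman")), 0.9)
})

test_that("important-wavelength selection finds loading peaks", {
  wl <- seq(1300, 1600, by = 2)
  bump <- function(c0, h = 1) h * exp(-(wl - c0)^2 / (2 * 8^2))
  fake <- structure(list(loadings = cbind(bump(1454)), wavelengths = wl),
                    class = "pca_model")
  expect_equal(select_important_wavelengths(fake, pcs = 1), 1454)
  fake2 <- structure(list(loadings = cbind(bump(1394) + bump(1522)),
                          wavelengths = wl), class = "pca_model")
  expect_equal(select_important_wavelengths(fake2, pcs = 1), c(1394, 1522))
  # close peaks deduplicate, keeping the larger |loading|
  sharp <- function(c0, h = 1) h * exp(-(wl - c0)^2 / (2 * 2^2))
  fake3 <- structure(list(loadings = cbind(sharp(1400) + sharp(1408, 0.8)),
                          wavelengths = wl), class = "pca_model")
  sel <- select_important_wavelengths(fake3, pcs = 1, min_separation_nm = 10)
  expect_equal(sel, 1400)
  expect_warning(
    out <- select_important_wavelengths(fake, pcs = 1, prominence_frac = 2),
    "prominence")
  expect_length(out, 0L)
  # permutation-invariance to sample order on real data
  sim <- sim_extract_cached(1L)
  pre <- preprocess_pipeline(sim$spectra, first_overtone_cfg())
  set.seed(5)
  perm <- sample.int(n_spectra(pre))
  s1 <- select_important_wavelengths(pca_fit(pre, 2))
  s2 <- select_important_wavelengths(pca_fit(subset_spectra(pre, perm), 2))
  expect_equal(s1, s2)
  # qualitative reproduction: the selection is non-empty, sorted, and a
  # majority of peaks fall within 10 nm of a generator band centre (SNV
  # shifts apparent peak positions, and the reference wavelength lists
  # likewise contain peaks with no single-band attribution)
  centres <- c(default_water_bands()$center_nm, 1414, 1477, 1503)
  expect_gt(length(s1), 2L)
  expect_identical(s1, sort(s1))
  near <- vapply(s1, function(nm) min(abs(nm - centres)) <= 10, logical(1L))
  expect_gte(sum(near), 3L)
})

test_that("LDA separates separable classes and is honest on noise", {
  set.seed(2)
  n <- 40
  x <- rbind(matrix(rnorm(2 * n), n), matrix(rnorm(2 * n, mean = 8), n))
  wl <- c(1300, 1302)
  labels <- rep(c("a", "b"), each = n)
  xs <- spectra_set(wl, x, data.frame(sample_id = labels,
                                      replicate = rep(1:3, length.out = 2 * n)))
  m <- pca_lda_fit(xs, labels, n_pcs = 2)
  expect_equal(ncol(m$canonical_axes), 1L)
  expect_equal(unname(predict(m, xs)), labels)
  # root1 aligned with the centroid difference (up to sign, in PC space)
  cd <- colMeans(predict(m$pca, x[41:80, ])) - colMeans(predict(m$pca, x[1:40, ]))
  ang <- abs(sum(cd * m$canonical_axes[, 1])) /
    (sqrt(sum(cd^2)) * sqrt(sum(m$canonical_axes[, 1]^2)))
  expect_gt(ang, 0.99)

  # permuted labels: CV accuracy near chance (99% binomial band, n = 80)
  perm_labels <- sample(labels)
  cv <- crossval_lda(xs, perm_labels, cv_scheme("replicate_3fold"), n_pcs = 2)
  band <- 2.58 * sqrt(0.5 * 0.5 / (2 * n)) * 100
  expect_lt(abs(cv$accuracy_prediction_pct - 50), band + 15)
})

test_that("replicate-fold LDA cross-validation has no leakage by design", {
  # identically distributed classes: prediction accuracy ~ chance
  # (scaled-down simulation oracle: 40 repeats, pooled binomial band)
  set.seed(9)
  k <- 4L; per <- 6L
  hits <- 0L; total <- 0L
  for (r in 1:40) {
    ab <- matrix(rnorm(k * per * 8), k * per)
    xs <- spectra_set(seq(1300, by = 2, length.out = 8), ab,
                      data.frame(sample_id = "x",
                                 replicate = rep(1:3, length.out = k * per)))
    labels <- rep(seq_len(k), each = per)
    cv <- crossval_lda(xs, labels, cv_scheme("replicate_3fold"), n_pcs = 3)
    hits <- hits + sum(diag(cv$confusion))
    total <- total + sum(cv$confusion)
  }
  p0 <- 1 / k
  band <- 2.58 * sqrt(p0 * (1 - p0) / total)
  expect_lt(abs(hits / total - p0), band)
})

test_that("single-class cross-validation is trivially perfect", {
  xs <- toy_spectra(matrix(rnorm(18), 6), replicate = rep(1:3, 2))
  cv <- crossval_lda(xs, rep("only", 6), cv_scheme("replicate_3fold"))
  expect_equal(cv$accuracy_prediction_pct, 100)
  expect_equal(cv$accuracy_recognition_pct, 100)
})

test_that("fold construction partitions samples and respects groups", {
  sim <- sim_extract_cached(1L)
  sp <- sim$spectra
  f3 <- make_folds(sp, cv_scheme("replicate_3fold"))
  expect_equal(sort(unique(f3)), 1:3)
  expect_equal(unname(f3), sp$meta$replicate)
  f6 <- make_folds(sp, cv_scheme("group_kfold_by_time", k = 6, seed = 1))
  expect_equal(length(f6), 315L)
  # all spectra sharing a germination time share a fold
  expect_true(all(tapply(f6, sp$meta$germination_h,
                         function(v) length(unique(v))) == 1L))
  expect_equal(sort(unique(f6)), 1:6)
  # deterministic in the scheme seed
  expect_identical(f6, make_folds(sp, cv_scheme("group_kfold_by_time",
                                                k = 6, seed = 1)))
  expect_error(make_folds(toy_spectra(matrix(1:4, 2)),
                          cv_scheme("replicate_3fold")),
               class = "sproutspec_fold_design_error")
})

test_that("class missing from a calibration fold is a design error", {
  xs <- toy_spectra(matrix(rnorm(24), 6), replicate = c(1, 1, 2, 2, 3, 3))
  labels <- c("a", "a", "a", "a", "b", "b")   # 'b' lives only in replicate 3
  expect_error(crossval_lda(xs, labels, cv_scheme("replicate_3fold"), n_pcs = 2),
               class = "sproutspec_fold_design_error")
})
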