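test_that("generate_digits balances classes, stays in range, is deterministic", {
  s <- generate_digits(100, class_mix = 0.5, seed = 1)
  expect_equal(unname(table(s$labels)[c("6", "9")]), c(50L, 50L),
               ignore_attr = TRUE)
  expect_true(all(s$images >= 0 & s$images <= 1))
  expect_equal(dim(s$images), c(100L, 784L))
  s2 <- generate_digits(100, class_mix = 0.5, seed = 1)
  expect_identical(s$images, s2$images)
  expect_identical(s$labels, s2$labels)
  s3 <- generate_digits(100, class_mix = 0.5, seed = 2)
  expect_false(identical(s$images, s3$images))
  # uneven mixes honour round(n * class_mix)
  s4 <- generate_digits(10, class_mix = 0.3, seed = 1)
  expect_equal(sum(s4$labels == 6), 3L)
})

test_that("off-frame glyph parameter ranges are rejected with a clear message", {
  rr <- glyph_param_ranges(translation = c(14, 15))
  expect_error(generate_digits(5, param_ranges = rr, seed = 1),
               "outside the 28x28 frame")
  expect_error(glyph_param_ranges(scale = c(2, 1)), "non-decreasing")
})

test_that("generate_fmri: noiseless voxels are exact linear functions and ground truth is bookkept", {
  set.seed(4)
  F <- matrix(rnorm(30 * 16, 0, 0.3), 30, 16)
  st <- generate_fmri(F, n_voxels = 40, n_informative = 10, snr_r2 = 1,
                      seed = 2)
  expect_s3_class(st, "synthetic_study")
  recon <- F %*% st$encoding_weights +
    matrix(st$intercepts, 30, 40, byrow = TRUE)
  expect_equal(st$voxels[, st$informative_idx],
               recon[, st$informative_idx], tolerance = 1e-12)
  # informative_idx exactly indexes the nonzero columns of the weights
  expect_identical(which(colSums(abs(st$encoding_weights)) > 0),
                   st$informative_idx)
  expect_true(all(st$noise_sd[st$informative_idx] == 0))
  # determinism
  st2 <- generate_fmri(F, 40, 10, 1, seed = 2)
  expect_identical(st$voxels, st2$voxels)
})

test_that("generate_fmri contracts: degenerate inputs error or warn", {
  F <- matrix(rnorm(30 * 16), 30, 16)
  expect_error(generate_fmri(F[1:10, ], 20, 5, 1, seed = 1), "n >= 17")
  expect_error(generate_fmri(F, 20, 30, 0.9, seed = 1))
  expect_error(generate_fmri(F, 20, 5, 0, seed = 1), "snr_r2")
  expect_error(generate_fmri(F, 20, 5, 1.2, seed = 1), "snr_r2")
  Fz <- F; Fz[, 3] <- 1
  expect_warning(generate_fmri(Fz, 20, 5, 1, seed = 1), "zero-variance")
})

test_that("generate_fmri noise calibration: mean in-sample R^2 lands on target at n = 90", {
  # oracle: independent per-voxel OLS (16 features + intercept) via lm.fit
  n <- 90
  set.seed(10)
  F <- matrix(rnorm(n * 16, 0, 0.3), n, 16)
  X <- cbind(1, F)
  for (target in c(0.5, 0.9)) {
    st <- generate_fmri(F, n_voxels = 200, n_informative = 200,
                        snr_r2 = target, seed = 31)
    r2 <- apply(st$voxels, 2L, function(y) {
      fit <- stats::lm.fit(X, y)
      1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    })
    expect_lt(abs(mean(r2) - target), 0.05)
  }
})

test_that("uninformative voxels have null-level R^2 (~ p/(n-1))", {
  n <- 90
  set.seed(11)
  F <- matrix(rnorm(n * 16, 0, 0.3), n, 16)
  st <- generate_fmri(F, n_voxels = 300, n_informative = 0, snr_r2 = 0.9,
                      seed = 5)
  fit <- fit_voxel_encoding(F, st$voxels)
  expect_lt(abs(mean(fit$r_squared) - 16 / (n - 1)), 0.04)
})

test_that("IDX round trip preserves 8-bit-quantized images and honors headers", {
  s <- generate_digits(3, seed = 5)
  p <- withr::local_tempfile(fileext = ".idx")
  write_idx(s, p)
  back <- read_idx(p)
  expect_equal(nrow(back$images), 3L)
  expect_equal(back$side, 28L)
  expect_equal(back$images, round(s$images * 255) / 255, tolerance = 1e-12)
  # labels
  pl <- withr::local_tempfile(fileext = ".idx")
  write_idx(s$labels, pl)
  expect_identical(read_idx(pl), s$labels)
})

test_that("malformed IDX files are rejected with offsets named", {
  p <- withr::local_tempfile(fileext = ".idx")
  writeBin(as.raw(c(1, 2, 3, 4)), p)
  expect_error(read_idx(p), "magic bytes at offset 0")
  # valid header promising more payload than present
  con <- file(p, "wb")
  writeBin(as.raw(c(0, 0, 0x08, 3)), con)
  writeBin(c(2L, 28L, 28L), con, size = 4L, endian = "big")
  writeBin(as.raw(rep(0, 100)), con)
  close(con)
  expect_error(read_idx(p), "truncated IDX payload")
})

test_that("split_folds partitions, stratifies and is deterministic", {
  labels <- rep(c(6, 9), 50)
  f <- split_folds(100, 10, labels, seed = 1)
  expect_equal(unname(table(f)), rep(10L, 10L), ignore_attr = TRUE)
  for (k in 1:10)
    expect_equal(unname(table(labels[f == k])), c(5L, 5L), ignore_attr = TRUE)
  expect_identical(f, split_folds(100, 10, labels, seed = 1))
  # partition property over random non-stratified cases
  for (case in list(c(17, 4), c(23, 23), c(9, 2))) {
    fo <- split_folds(case[1], case[2], seed = case[1])
    expect_setequal(unique(fo), seq_len(case[2]))
    expect_length(fo, case[1])
    expect_lte(diff(range(table(fo))), 1)
  }
  expect_error(split_folds(5, 6), "must not exceed")
})
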