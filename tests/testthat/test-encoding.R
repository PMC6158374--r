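test_that("longer_capsule_features picks the larger-norm capsule, ties to the first", {
  caps <- rbind(c(0.9, rep(0, 15)), c(0.2, rep(0, 15)))
  expect_equal(unname(longer_capsule_features(caps))[1], 0.9)
  expect_equal(attr(longer_capsule_features(caps), "which"), 1L)
  expect_equal(attr(longer_capsule_features(caps[2:1, ]), "which"), 2L)
  tie <- rbind(c(0.5, rep(0, 15)), c(0, 0.5, rep(0, 14)))
  expect_equal(attr(longer_capsule_features(tie), "which"), 1L)
  # batch form
  arr <- array(0, c(3, 2, 16))
  arr[1, 1, 1] <- 0.9; arr[1, 2, 1] <- 0.1
  arr[2, 1, 1] <- 0.1; arr[2, 2, 2] <- 0.8
  arr[3, 1, 3] <- 0.4; arr[3, 2, 4] <- 0.4   # exact tie
  f <- longer_capsule_features(arr)
  expect_equal(attr(f, "which"), c(1L, 2L, 1L))
  expect_equal(f[2, 2], 0.8)
})

test_that("fit_voxel_encoding: exact fits, constant voxels and R^2 recomputation", {
  set.seed(3)
  n <- 40
  F <- matrix(rnorm(n * 16), n, 16)
  W <- matrix(rnorm(16 * 5), 16, 5)
  Y <- cbind(F %*% W + 2,                           # 5 exact voxels
             matrix(rnorm(n * 5), n, 5),            # 5 noise voxels
             rep(1.5, n))                           # constant voxel
  expect_warning(fit <- fit_voxel_encoding(F, Y), "constant voxel")
  expect_equal(fit$r_squared[1:5], rep(1, 5), tolerance = 1e-10)
  expect_equal(fit$r_squared[11], 0)
  expect_true(all(fit$r_squared <= 1))
  # independent recomputation of R^2 from residuals via lm()
  for (j in c(2, 7, 9)) {
    lmfit <- lm(Y[, j] ~ F)
    r2 <- 1 - sum(residuals(lmfit)^2) / sum((Y[, j] - mean(Y[, j]))^2)
    expect_equal(fit$r_squared[j], r2, tolerance = 1e-10)
  }
  expect_error(fit_voxel_encoding(F[1:10, ], Y[1:10, ]), "need n >")
})

test_that("select_top_k: exact count, index tie-break, permutation equivariance", {
  fit <- structure(list(r_squared = c(0.5, 0.9, 0.9, 0.1, 0.7)),
                   class = "encoding_fit")
  sel <- select_top_k(fit, 3)
  expect_equal(sel$selected, c(2L, 3L, 5L))
  expect_equal(sel$ranked_indices[1:2], c(2L, 3L))  # tie -> ascending index
  expect_equal(sum(sel$mask), 3L)
  expect_error(select_top_k(fit, 6), "exceeds")
  selV <- select_top_k(fit, 5)
  expect_equal(selV$selected, 1:5)                  # k = V keeps everything
  # permutation equivariance on a real fit
  set.seed(8)
  F <- matrix(rnorm(60 * 16), 60, 16)
  st <- generate_fmri(F, 50, 10, 0.9, seed = 2)
  f1 <- fit_voxel_encoding(F, st$voxels)
  perm <- sample(50)
  f2 <- fit_voxel_encoding(F, st$voxels[, perm])
  s1 <- select_top_k(f1, 10)$selected
  s2 <- select_top_k(f2, 10)$selected
  expect_setequal(match(s1, perm), s2)
})

test_that("pure-noise voxels never displace noiseless informative voxels from the top-k", {
  n <- 90
  for (seed in 1:10) {
    set.seed(seed)
    F <- matrix(rnorm(n * 16, 0, 0.3), n, 16)
    st <- generate_fmri(F, n_voxels = 220, n_informative = 20, snr_r2 = 1,
                        seed = seed)
    sel <- select_top_k(fit_voxel_encoding(F, st$voxels), 20)
    expect_identical(sel$selected, st$informative_idx)
  }
})

test_that("evaluate_encoding: perfect recovery when noiseless, null voxels near zero", {
  n <- 90
  set.seed(12)
  F <- matrix(rnorm(n * 16, 0, 0.3), n, 16)
  st <- generate_fmri(F, 60, 30, 1, seed = 6)
  ev <- evaluate_encoding(F, st$voxels, st$informative_idx, folds = 10,
                          seed = 2)
  expect_equal(ev$mean_correlation, 1, tolerance = 1e-6)
  # null-voxel correlations are small in absolute value (20 seeds)
  vals <- sapply(1:20, function(sd) {
    stn <- generate_fmri(F, 30, 0, 0.9, seed = 100 + sd)
    evn <- evaluate_encoding(F, stn$voxels, NULL, folds = 10, seed = 2)
    mean(abs(evn$per_voxel), na.rm = TRUE)
  })
  expect_lt(mean(vals), 0.2)
})

test_that("encoding CV correlation decreases from top-50 to top-500 on a mixed study", {
  n <- 90
  set.seed(13)
  F <- matrix(rnorm(n * 16, 0, 0.3), n, 16)
  st <- generate_fmri(F, 3092, 50, 0.9, seed = 17)
  fit <- fit_voxel_encoding(F, st$voxels)
  fold <- split_folds(n, 10, seed = 3)
  m50 <- evaluate_encoding(F, st$voxels, select_top_k(fit, 50), fold)
  m500 <- evaluate_encoding(F, st$voxels, select_top_k(fit, 500), fold)
  expect_gt(m50$mean_correlation, m500$mean_correlation)
})
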