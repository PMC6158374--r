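make_caps_targets <- function(n, seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(n * 2 * 16, 0, 0.2), c(n, 2, 16))
  arr
}

test_that("predict_capsules: squash bound, determinism, zero network, shape errors", {
  cfg <- mapper_config(hidden = c(12L, 8L), iterations = 0L, seed = 2)
  mp <- train_mapper(matrix(rnorm(20 * 10), 20), make_caps_targets(20), cfg)
  set.seed(4)
  X <- matrix(rnorm(30 * 10, 0, 5), 30)
  v <- predict_capsules(mp, X)
  norms <- sqrt(apply(v^2, c(1, 2), sum))
  expect_true(all(norms < 1))
  expect_identical(predict_capsules(mp, X[1, ]), predict_capsules(mp, X[1, ]))
  mp0 <- mp
  for (nm in names(mp0$params)) mp0$params[[nm]][] <- 0
  expect_true(all(predict_capsules(mp0, X) == 0))
  expect_error(predict_capsules(mp, rnorm(7)), "expects")
})

test_that("zero iterations returns the initialized model unchanged", {
  X <- matrix(rnorm(20 * 10), 20)
  cfg <- mapper_config(iterations = 0L, seed = 9, standardize = FALSE)
  mp <- train_mapper(X, make_caps_targets(20), cfg)
  ref <- capsrecon:::.init_mapper(10L, cfg)
  expect_identical(mp$params, ref)
  expect_error(train_mapper(X[1:5, ], make_caps_targets(5),
                            mapper_config(batch = 10L)), "batch size")
})

test_that("mapper objective gradients (MSE + L2, through the squash) match finite differences", {
  cfg <- mapper_config(hidden = c(7L, 5L), l2_strength = 1e-2, seed = 3)
  params <- capsrecon:::.init_mapper(6L, cfg)
  set.seed(5)
  X <- matrix(rnorm(12 * 6), 12)
  Y <- make_caps_targets(12, seed = 6)
  lg <- capsrecon:::.mapper_loss_grad(params, X, Y, cfg)
  loss_at <- function(p)
    capsrecon:::.mapper_loss_grad(p, X, Y, cfg, grads = FALSE)$loss
  set.seed(7)
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), 2)) {
      p <- params; eps <- 1e-5
      p[[nm]][i] <- p[[nm]][i] + eps; lp <- loss_at(p)
      p[[nm]][i] <- p[[nm]][i] - 2 * eps; lm <- loss_at(p)
      expect_lt(rel_err((lp - lm) / (2 * eps), lg$grads[[nm]][i]), 1e-4)
    }
  }
})

test_that("stronger L2 never increases final weight norms (3 levels, fixed seed)", {
  set.seed(21)
  X <- matrix(rnorm(40 * 10), 40)
  Y <- make_caps_targets(40, seed = 22)
  norms <- sapply(c(0, 1e-3, 1e-1), function(l2) {
    mp <- train_mapper(X, Y, mapper_config(hidden = c(16L, 12L),
                                           iterations = 400L, lr = 1e-3,
                                           l2_strength = l2, seed = 30))
    sqrt(sum(mp$params$W1^2) + sum(mp$params$W2^2))
  })
  expect_true(all(diff(norms) <= 0))
})

test_that("training reduces the loss and records train/test traces", {
  set.seed(31)
  X <- matrix(rnorm(40 * 10), 40)
  W <- matrix(rnorm(10 * 32, 0, 0.1), 10, 32)
  Z <- X %*% W
  Y <- array(0, c(40, 2, 16))
  Y[, 1, ] <- squash(Z[, 1:16]); Y[, 2, ] <- squash(Z[, 17:32])
  mp <- train_mapper(X[1:30, ], Y[1:30, , ],
                     mapper_config(iterations = 1000L, lr = 1e-3, seed = 8),
                     test_voxels = X[31:40, ], test_capsules = Y[31:40, , ])
  expect_lt(utils::tail(mp$trace$train_mse, 1), mp$trace$train_mse[1])
  expect_true(all(is.finite(mp$trace$test_mse)))
  expect_lt(utils::tail(mp$trace$test_mse, 1), mp$trace$test_mse[1])
})
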