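test_that("squash matches its closed forms and preserves direction", {
  expect_identical(squash(rep(0, 8)), rep(0, 8))
  v1 <- squash(c(1, rep(0, 7)))
  expect_equal(sqrt(sum(v1^2)), 0.5)
  set.seed(1)
  d <- rnorm(16); d <- d / sqrt(sum(d^2))
  v3 <- squash(3 * d)
  expect_equal(sqrt(sum(v3^2)), 0.9)
  expect_equal(v3 / sqrt(sum(v3^2)), d)          # direction preserved
  # squash bound + monotonicity over a wide norm grid (matrix form)
  norms <- 10^seq(-6, 3, length.out = 200)
  M <- norms * matrix(rep(d, each = 200), 200)
  out <- sqrt(rowSums(squash(M)^2))
  expect_true(all(out < 1))
  expect_true(all(diff(out) > 0))
  expect_gt(max(out), 0.999)
})

test_that("shape arithmetic holds by construction on a reduced network", {
  m <- tiny_capsnet()
  img <- matrix(runif(784), 1)
  pc <- capsnet_primary(m, img)
  expect_equal(pc$conv1_dim, c(20, 20, 4))
  expect_equal(pc$grid_dim, c(6, 6, 2))
  expect_equal(dim(pc$capsules), c(1L, 72L, 8L))   # 6*6*2 capsules
  pr <- predict_capsnet(m, img)
  expect_equal(dim(pr$capsules), c(1L, 2L, 16L))
  expect_error(capsnet_primary(m, matrix(runif(100), 1)), "expected 784")
})

test_that("all-zero image with zero biases yields all-zero capsules", {
  m <- tiny_capsnet()
  pc <- capsnet_primary(m, rep(0, 784))
  expect_true(all(pc$capsules == 0))
  pr <- predict_capsnet(m, rep(0, 784))
  expect_true(all(pr$capsules == 0))
})

test_that("routing: uniform couplings at start, degenerate single-capsule case", {
  set.seed(2)
  uhat <- array(rnorm(5 * 2 * 4), c(5, 2, 4))
  rt1 <- route_capsules(uhat, iterations = 1L)
  expect_equal(unname(rt1$couplings), matrix(0.5, 5, 2))  # softmax of zeros
  u1 <- array(rnorm(5 * 1 * 4), c(5, 1, 4))
  for (iters in c(1L, 3L))
    expect_equal(unname(route_capsules(u1, iters)$couplings),
                 matrix(1, 5, 1))
  expect_error(route_capsules(uhat * NA), "non-finite")
  expect_error(route_capsules(uhat, 0L))
})

test_that("routing matches the literal equation-by-equation oracle to 1e-10", {
  set.seed(7)
  for (case in 1:20) {
    n_low <- sample(2:5, 1); J <- sample(2:3, 1); D <- sample(2:4, 1)
    iters <- sample(1:4, 1)
    uhat <- array(rnorm(n_low * J * D), c(n_low, J, D))
    states <- oracle_route(uhat, iters)
    rt <- route_capsules(uhat, iters)
    final <- states[[iters]]
    expect_equal(unname(rt$couplings), final$c, tolerance = 1e-10)
    expect_equal(unname(rt$logits), final$b, tolerance = 1e-10)
    vmat <- t(sapply(seq_len(J), function(j) rt$v[j, ]))
    expect_equal(unname(vmat), final$v, tolerance = 1e-10)
    # coupling rows sum to one at every iteration
    for (st in states)
      expect_equal(rowSums(st$c), rep(1, n_low), tolerance = 1e-12)
  }
})

test_that("agreeing capsules out-couple a dissenter after three iterations", {
  # two lower capsules predict +e1 for upper A; one predicts -e1;
  # predictions for upper B are small noise
  D <- 4
  uhat <- array(0, c(3, 2, D))
  uhat[1, 1, ] <- c(1, 0, 0, 0)
  uhat[2, 1, ] <- c(1, 0.05, 0, 0)
  uhat[3, 1, ] <- c(-1, 0, 0, 0)
  uhat[, 2, ] <- 0.01
  rt <- route_capsules(uhat, iterations = 3L)
  expect_gt(rt$couplings[1, 1], rt$couplings[3, 1])
  expect_gt(rt$couplings[2, 1], rt$couplings[3, 1])
  expect_gt(rt$couplings[1, 1], 0.5)
})

test_that("margin loss reproduces its worked values and rejects bad targets", {
  expect_equal(margin_loss(c(0.9, 0.1), c(1, 0)), 0)
  expect_equal(margin_loss(c(0, 0), c(1, 0)), 0.81)
  expect_equal(margin_loss(c(0.5, 0.5), c(1, 0)), 0.24)
  # batch form averages per-item sums
  L <- margin_loss(rbind(c(0.9, 0.1), c(0.5, 0.5)), rbind(c(1, 0), c(1, 0)))
  expect_equal(L, 0.12)
  expect_error(margin_loss(c(0.5, 0.5), c(1, 1)), "one-hot")
  expect_error(margin_loss(c(0.5, 0.5), c(0.2, 0.8)), "one-hot")
})

test_that("overall loss composes margin and weighted reconstruction MSE", {
  img <- runif(784)
  expect_equal(overall_loss(0.24, img, img, mu = 4), 0.24)
  rec <- img + 0.1
  expect_equal(overall_loss(0.24, img, rec, mu = 4), 0.24 + 4 * 0.01)
  expect_error(overall_loss(0.1, img, img[-1]), "extent")
})

test_that("decoder is deterministic and collapses to sigmoid(bias) at zero", {
  m <- tiny_capsnet()
  cap <- rnorm(16)
  expect_identical(decode_capsule(m, cap), decode_capsule(m, cap))
  m0 <- m
  for (nm in c("DW1", "Db1", "DW2", "Db2", "DW3"))
    m0$params[[nm]][] <- 0
  m0$params$Db3[] <- 0.3
  expect_equal(decode_capsule(m0, rep(0, 16)),
               rep(1 / (1 + exp(-0.3)), 784))
  expect_error(decode_capsule(m, rnorm(5)), "16 components")
})

test_that("analytic gradients match central finite differences", {
  cfg <- capsnet_config(conv1_filters = 4L, primary_maps = 2L,
                        decoder_hidden = c(8L, 12L), seed = 3L)
  model <- init_capsnet(cfg)
  g <- capsrecon:::.capsnet_geom(cfg, scatter = TRUE)
  set.seed(5)
  X <- matrix(runif(2 * 784), 2)
  li <- c(1L, 2L)
  lg <- capsrecon:::.capsnet_loss_grad(model$params, cfg, g, X, li)
  loss_at <- function(params)
    capsrecon:::.capsnet_loss_grad(params, cfg, g, X, li, grads = FALSE)$loss
  set.seed(9)
  # 2 random coordinates in every parameter group (22 checks total)
  for (nm in names(model$params)) {
    for (i in sample(length(model$params[[nm]]), 2)) {
      p <- model$params; eps <- 1e-5
      p[[nm]][i] <- p[[nm]][i] + eps; lp <- loss_at(p)
      p[[nm]][i] <- p[[nm]][i] - 2 * eps; lm <- loss_at(p)
      fd <- (lp - lm) / (2 * eps)
      expect_lt(rel_err(fd, lg$grads[[nm]][i]), 1e-4)
    }
  }
})

test_that("one small gradient step on a batch of 10 reduces that batch's loss", {
  cfg <- capsnet_config(conv1_filters = 4L, primary_maps = 2L,
                        decoder_hidden = c(8L, 12L), seed = 3L)
  model <- init_capsnet(cfg)
  g <- capsrecon:::.capsnet_geom(cfg, scatter = TRUE)
  s <- generate_digits(10, seed = 13)
  li <- match(s$labels, cfg$classes)
  lg <- capsrecon:::.capsnet_loss_grad(model$params, cfg, g, s$images, li)
  p2 <- model$params
  for (nm in names(p2)) p2[[nm]] <- p2[[nm]] - 1e-3 * lg$grads[[nm]]
  l2 <- capsrecon:::.capsnet_loss_grad(p2, cfg, g, s$images, li,
                                       grads = FALSE)$loss
  expect_lt(l2, lg$loss)
})

test_that("training contracts: class coverage and label domain are enforced", {
  s <- generate_digits(10, class_mix = 1, seed = 1)   # all class 6
  expect_error(train_capsnet(s, config = scaled_capsnet_config(epochs = 1L)),
               "at least 2 classes")
  s2 <- generate_digits(10, seed = 1)
  expect_error(train_capsnet(s2$images, rep(c(1, 2), 5),
                             config = scaled_capsnet_config(epochs = 1L)),
               "outside config")
})
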