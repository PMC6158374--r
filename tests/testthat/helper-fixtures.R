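# Shared fixtures (trained once per test session) and independent oracles.

.fx <- new.env(parent = emptyenv())

# the desk-scale stage-1 run used across acceptance and module tests:
# 500 synthetic glyphs, scaled architecture, 20 epochs
fixture_capsnet <- function() {
  if (is.null(.fx$capsnet)) {
    .fx$stimuli <- generate_digits(500, seed = 7)
    .fx$capsnet <- train_capsnet(.fx$stimuli,
                                 config = scaled_capsnet_config(seed = 11L))
  }
  .fx$capsnet
}

fixture_stimuli <- function() {
  fixture_capsnet()
  .fx$stimuli
}

# noiseless synthetic study whose voxels are linear in the trained network's
# longer-capsule features (100 stimuli, 3092 voxels, 50 informative)
fixture_study <- function() {
  if (is.null(.fx$study)) {
    model <- fixture_capsnet()
    stim <- generate_digits(100, seed = 21)
    pr <- predict_capsnet(model, stim$images)
    feats <- longer_capsule_features(pr$capsules)
    .fx$study <- generate_fmri(feats, n_voxels = 3092, n_informative = 50,
                               snr_r2 = 1, seed = 3, images = stim$images,
                               labels = stim$labels)
    .fx$study_pr <- pr
    .fx$study_feats <- feats
    .fx$study_stim <- stim
  }
  .fx$study
}

fixture_study_capsules <- function() {
  fixture_study()
  .fx$study_pr$capsules
}

fixture_study_features <- function() {
  fixture_study()
  .fx$study_feats
}

# mapper trained on the first 90 study items at full defaults, with the last
# 10 tracked as a test set
fixture_mapper <- function() {
  if (is.null(.fx$mapper)) {
    study <- fixture_study()
    caps <- fixture_study_capsules()
    feats <- fixture_study_features()
    sel <- select_top_k(fit_voxel_encoding(feats[1:90, ],
                                           study$voxels[1:90, ]), 100)
    .fx$mapper_sel <- sel
    .fx$mapper <- train_mapper(
      study$voxels[1:90, sel$selected], caps[1:90, , ],
      mapper_config(seed = 5),
      test_voxels = study$voxels[91:100, sel$selected],
      test_capsules = caps[91:100, , ])
  }
  .fx$mapper
}

fixture_mapper_selection <- function() {
  fixture_mapper()
  .fx$mapper_sel
}

# full 10-fold cross-validated evaluation on the noiseless study
fixture_cv <- function() {
  if (is.null(.fx$cv))
    .fx$cv <- crossvalidate(fixture_study(), fixture_capsnet(), k = 10,
                            seed = 9)
  .fx$cv
}

# a small untrained capsule network for shape/gradient/plumbing tests
tiny_capsnet <- function(seed = 3L) {
  init_capsnet(capsnet_config(conv1_filters = 4L, primary_maps = 2L,
                              decoder_hidden = c(8L, 12L), seed = seed))
}

# ---- independent oracles ----------------------------------------------------

# literal transcription of the routing equations for one item:
# c_ij = softmax over j of b_ij; s_j = sum_i c_ij uhat_ij; v_j = squash(s_j);
# b_ij <- b_ij + uhat_ij . v_j.  Returns full per-iteration state.
oracle_route <- function(uhat, iterations) {
  n_low <- dim(uhat)[1]; J <- dim(uhat)[2]; D <- dim(uhat)[3]
  b <- matrix(0, n_low, J)
  states <- list()
  for (t in seq_len(iterations)) {
    cc <- t(apply(b, 1L, function(row) exp(row) / sum(exp(row))))
    cc <- matrix(cc, n_low, J)
    v <- matrix(0, J, D)
    for (j in seq_len(J)) {
      s <- rep(0, D)
      for (i in seq_len(n_low)) s <- s + cc[i, j] * uhat[i, j, ]
      ns <- sqrt(sum(s^2))
      v[j, ] <- if (ns > 0) (ns^2 / (1 + ns^2)) * s / ns else s * 0
    }
    for (i in seq_len(n_low)) for (j in seq_len(J))
      b[i, j] <- b[i, j] + sum(uhat[i, j, ] * v[j, ])
    states[[t]] <- list(c = cc, v = v, b = b)
  }
  states
}

# independently coded SSIM: explicit double loops over valid window centers
oracle_ssim <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01,
                        k2 = 0.03, L = 1) {
  side <- as.integer(sqrt(length(a)))
  A <- matrix(as.numeric(a), side); B <- matrix(as.numeric(b), side)
  half <- (window - 1L) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2)); g1 <- g1 / sum(g1)
  W <- outer(g1, g1)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  vals <- c()
  for (r in (half + 1):(side - half)) for (cl in (half + 1):(side - half)) {
    pa <- A[(r - half):(r + half), (cl - half):(cl + half)]
    pb <- B[(r - half):(r + half), (cl - half):(cl + half)]
    mua <- sum(W * pa); mub <- sum(W * pb)
    va <- sum(W * pa^2) - mua^2; vb <- sum(W * pb^2) - mub^2
    cab <- sum(W * pa * pb) - mua * mub
    vals <- c(vals, ((2 * mua * mub + c1) * (2 * cab + c2)) /
                ((mua^2 + mub^2 + c1) * (va + vb + c2)))
  }
  mean(vals)
}

# central finite difference of f at x[idx]
fd_grad <- function(f, x, idx, eps = 1e-5) {
  xp <- x; xp[idx] <- xp[idx] + eps
  xm <- x; xm[idx] <- xm[idx] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-8)

# shift a column-major 28x28 image by (dr, dc) pixels, zero-filling
shift_image <- function(img, dr, dc, side = 28L) {
  m <- matrix(img, side, side)
  out <- matrix(0, side, side)
  rs <- seq_len(side) - dr; cs <- seq_len(side) - dc
  ok_r <- rs >= 1 & rs <= side; ok_c <- cs >= 1 & cs <= side
  out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
  as.vector(out)
}
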