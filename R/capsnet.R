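#' Squashing nonlinearity for capsule vectors
#'
#' Compresses a vector's norm into `[0, 1)` while preserving its direction:
#' `v = (||s||^2 / (1 + ||s||^2)) * s / ||s||`, implemented in the
#' singularity-free form `v = s * ||s|| / (1 + ||s||^2)` so the zero vector
#' maps to zero without a division guard.  An input of norm 1 comes out with
#' norm 0.5; norm 3 comes out with norm 0.9; the output norm approaches but
#' never reaches 1.
#'
#' @param x a numeric vector (one capsule) or a matrix whose rows are
#'   capsules.
#' @return Same shape as `x`.
#' @export
#' @examples
#' sqrt(sum(squash(c(3, 0, 0))^2))  # 0.9
squash <- function(x) {
  if (is.null(dim(x))) {
    r2 <- sum(x * x)
    return(x * sqrt(r2) / (1 + r2))
  }
  r2 <- rowSums(x * x)
  x * (sqrt(r2) / (1 + r2))
}

# backward of row-wise squash: M pre-activation (rows = capsules), r = norms
.squash_backward <- function(dV, M, r) {
  f <- r / (1 + r^2)
  fp <- (1 - r^2) / (1 + r^2)^2
  sdot <- rowSums(M * dV)
  dV * f + M * (fp / pmax(r, 1e-9) * sdot)
}

#' Capsule network configuration
#'
#' Architecture and training hyperparameters.  Defaults are the full-width
#' network: a 9x9/stride-1 convolution with 256 filters and ReLU (28x28 ->
#' 20x20 feature maps), a 9x9/stride-2 convolution forming 32 maps of 6x6
#' 8-D primary capsules (1152 capsules), dynamic routing (3 iterations) to
#' one 16-D capsule per class, and a three-layer fully connected decoder
#' (ReLU, ReLU, sigmoid) reconstructing the 784-pixel image from a single
#' 16-D capsule.  The margin-loss constants are `m_plus = 0.9`,
#' `m_minus = 0.1`, `lambda_down = 0.5`; the reconstruction loss is
#' `mu = 4` times the pixel-mean squared error.  Training uses Adam with
#' batch size 10 for ~20 epochs.
#'
#' @param side input image side (pixels).
#' @param conv1_filters filters in the first convolution.
#' @param primary_maps number of primary-capsule maps.
#' @param primary_dim components per primary capsule.
#' @param digit_dim components per class capsule.
#' @param classes class labels, in capsule order (first = lower label, used
#'   for tie-breaks).
#' @param ksize convolution kernel size.
#' @param routing_iters dynamic-routing iterations.
#' @param decoder_hidden sizes of the two decoder hidden layers.
#' @param m_plus,m_minus,lambda_down margin-loss constants.
#' @param mu weight of the reconstruction (pixel-mean MSE) loss term.
#' @param lr,beta1,beta2,adam_eps Adam hyperparameters.
#' @param batch minibatch size.
#' @param epochs training epochs.
#' @param w_init_sd s.d. of the Gaussian init for routing transform weights.
#' @param seed integer seed for initialization and batch shuffling.
#' @return A list of class `"capsnet_config"`.
#' @export
capsnet_config <- function(side = 28L, conv1_filters = 256L,
                           primary_maps = 32L, primary_dim = 8L,
                           digit_dim = 16L, classes = c(6L, 9L),
                           ksize = 9L, routing_iters = 3L,
                           decoder_hidden = c(512L, 1024L),
                           m_plus = 0.9, m_minus = 0.1, lambda_down = 0.5,
                           mu = 4, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                           adam_eps = 1e-8, batch = 10L, epochs = 20L,
                           w_init_sd = 0.1, seed = 1L) {
  stopifnot(0 < m_minus, m_minus < m_plus, m_plus < 1, length(classes) >= 2)
  cfg <- as.list(environment())
  cfg$n_classes <- length(classes)
  structure(cfg, class = "capsnet_config")
}

#' Scaled-down capsule network configuration for desk-scale training
#'
#' Same architecture family with 64 first-layer filters and 8 primary maps
#' (288 primary capsules), sized so that a 500-image / 20-epoch training run
#' finishes in minutes on one CPU.  All loss constants and the training
#' protocol are unchanged.
#'
#' @param ... overrides passed to [capsnet_config()].
#' @export
scaled_capsnet_config <- function(...) {
  capsnet_config(conv1_filters = 32L, primary_maps = 8L,
                 decoder_hidden = c(128L, 256L), ...)
}

# geometry caches derived from a config; an environment so gather indices and
# scatter matrices computed per batch size are memoized across batches
.capsnet_geom <- function(cfg, scatter = FALSE) {
  g <- new.env(parent = emptyenv())
  g$ci1 <- conv_index(cfg$side, cfg$side, 1L, cfg$ksize, 1L)
  g$c2 <- cfg$primary_maps * cfg$primary_dim
  g$ci2 <- conv_index(g$ci1$oh, g$ci1$ow, cfg$conv1_filters, cfg$ksize, 2L)
  g$n_low <- g$ci2$n_pos * cfg$primary_maps
  g$S2 <- if (scatter) conv_scatter(g$ci2) else NULL
  g$G <- list()
  g
}

# memoized flat gather indices for batch size n
.gidx <- function(g, n) {
  key <- as.character(n)
  if (is.null(g$G[[key]]))
    g$G[[key]] <- list(G1 = conv_gather_index(g$ci1, n),
                       G2 = conv_gather_index(g$ci2, n))
  g$G[[key]]
}

#' Initialize a capsule network
#'
#' Convolution kernels and decoder weights use fan-in-scaled Gaussian
#' initialization; routing transform weights are zero-mean Gaussian with s.d.
#' `w_init_sd`; biases start at zero.
#'
#' @param config a [capsnet_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return An object of class `"capsnet_model"`.
#' @export
init_capsnet <- function(config = capsnet_config(), seed = config$seed) {
  cfg <- config
  g <- .capsnet_geom(cfg)
  local_seed(seed, {
    he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
    p1 <- cfg$ksize^2
    p2 <- cfg$ksize^2 * cfg$conv1_filters
    dh <- cfg$decoder_hidden
    params <- list(
      K1 = he(p1, cfg$conv1_filters), bc1 = numeric(cfg$conv1_filters),
      K2 = he(p2, g$c2), bc2 = numeric(g$c2),
      W = array(stats::rnorm(g$n_low * cfg$n_classes * cfg$digit_dim *
                               cfg$primary_dim, 0, cfg$w_init_sd),
                c(g$n_low, cfg$n_classes, cfg$digit_dim, cfg$primary_dim)),
      DW1 = he(cfg$digit_dim, dh[1]), Db1 = numeric(dh[1]),
      DW2 = he(dh[1], dh[2]), Db2 = numeric(dh[2]),
      DW3 = matrix(stats::rnorm(dh[2] * cfg$side^2, 0, sqrt(1 / dh[2])),
                   dh[2], cfg$side^2),
      Db3 = numeric(cfg$side^2))
    structure(list(config = cfg, params = params, trace = NULL, seed = seed),
              class = "capsnet_model")
  })
}

#' @export
print.capsnet_model <- function(x, ...) {
  cfg <- x$config
  g <- .capsnet_geom(cfg)
  cat(sprintf(paste0("<capsnet_model> %dx%d -> conv(%d) %dx%d -> %d primary",
                     " capsules (%d maps of %dx%d, %d-D) -> %d x %d-D class",
                     " capsules\n"),
              cfg$side, cfg$side, cfg$conv1_filters, g$ci1$oh, g$ci1$ow,
              g$n_low, cfg$primary_maps, g$ci2$oh, g$ci2$ow, cfg$primary_dim,
              cfg$n_classes, cfg$digit_dim))
  if (!is.null(x$trace))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                length(x$trace$loss), utils::tail(x$trace$loss, 1)))
  invisible(x)
}

# ---- forward passes ---------------------------------------------------------

# images X: n x side^2 -> caches up to squashed primary capsules
.forward_to_primary <- function(params, cfg, g, X) {
  n <- nrow(X)
  gi <- .gidx(g, n)
  c1 <- conv_forward(X, params$K1, params$bc1, g$ci1, gi$G1)
  H1 <- relu(c1$Y)
  X2 <- H1
  dim(X2) <- c(n, g$ci1$n_pos * cfg$conv1_filters)
  c2 <- conv_forward(X2, params$K2, params$bc2, g$ci2, gi$G2)
  U <- array(c2$Y, c(n, g$ci2$n_pos, cfg$primary_dim, cfg$primary_maps))
  U <- aperm(U, c(1L, 2L, 4L, 3L))
  M <- matrix(U, n * g$n_low, cfg$primary_dim)
  r <- sqrt(rowSums(M * M))
  Uv <- M * (r / (1 + r^2))
  list(n = n, c1 = c1, H1 = H1, c2 = c2, M = M, r = r, Uv = Uv)
}

# prediction vectors: list over upper capsule j of Hj = (n*n_low) x D,
# Hj[b + (i-1)n, d] = W[i, j, d, ] . u[b, i, ]
.forward_uhat <- function(params, cfg, g, Uv, n) {
  J <- cfg$n_classes; D <- cfg$digit_dim
  rep_i <- rep(seq_len(g$n_low), each = n)
  lapply(seq_len(J), function(j) {
    Hj <- matrix(0, n * g$n_low, D)
    for (k in seq_len(cfg$primary_dim)) {
      Wjk <- matrix(params$W[, j, , k], g$n_low, D)
      Hj <- Hj + Uv[, k] * Wjk[rep_i, , drop = FALSE]
    }
    Hj
  })
}

# split each Hj into per-dimension n x n_low matrices for the routing loop
.uhat_views <- function(uhat_list, n, n_low, D) {
  lapply(uhat_list, function(Hj)
    lapply(seq_len(D), function(d) matrix(Hj[, d], n, n_low)))
}

# softmax over the upper index j for a list of n x n_low logit matrices
.softmax_list <- function(b) {
  bmax <- Reduce(pmax, b)
  e <- lapply(b, function(bj) exp(bj - bmax))
  denom <- Reduce(`+`, e)
  lapply(e, function(ej) ej / denom)
}

# core routing loop on the view layout
.route_forward <- function(Uv_jd, iterations, n, n_low, J, D) {
  b <- rep(list(matrix(0, n, n_low)), J)
  cache <- vector("list", iterations)
  for (t in seq_len(iterations)) {
    cc <- .softmax_list(b)
    s <- lapply(seq_len(J), function(j)
      vapply(seq_len(D), function(d) rowSums(cc[[j]] * Uv_jd[[j]][[d]]),
             numeric(n)))
    v <- lapply(s, function(sj) {
      sj <- matrix(sj, n, D)
      r <- sqrt(rowSums(sj * sj))
      list(v = sj * (r / (1 + r^2)), r = r, s = sj)
    })
    cache[[t]] <- list(c = cc, v = v)
    for (j in seq_len(J)) {
      agree <- matrix(0, n, n_low)
      for (d in seq_len(D)) agree <- agree + Uv_jd[[j]][[d]] * v[[j]]$v[, d]
      b[[j]] <- b[[j]] + agree
    }
  }
  list(v = lapply(cache[[iterations]]$v, `[[`, "v"),
       couplings = cache[[iterations]]$c, logits = b, cache = cache)
}

# backward through the routing loop; dv: list over j of n x D gradients
.route_backward_core <- function(dv, Uv_jd, cache, n, n_low, J, D) {
  iterations <- length(cache)
  duhat <- lapply(seq_len(J), function(j) matrix(0, n * n_low, D))
  db <- rep(list(matrix(0, n, n_low)), J)
  dv_cur <- dv
  for (t in rev(seq_len(iterations))) {
    st <- cache[[t]]
    dc <- vector("list", J)
    for (j in seq_len(J)) {
      vj <- st$v[[j]]
      ds <- .squash_backward(dv_cur[[j]], vj$s, vj$r)   # n x D
      dcj <- matrix(0, n, n_low)
      cj <- st$c[[j]]
      for (d in seq_len(D)) {
        dcj <- dcj + ds[, d] * Uv_jd[[j]][[d]]
        duhat[[j]][, d] <- duhat[[j]][, d] + as.vector(cj * ds[, d])
      }
      dc[[j]] <- dcj
    }
    inner <- Reduce(`+`, Map(`*`, dc, st$c))
    for (j in seq_len(J)) db[[j]] <- db[[j]] + st$c[[j]] * (dc[[j]] - inner)
    if (t > 1L) {
      vprev <- cache[[t - 1L]]$v
      dv_cur <- vector("list", J)
      for (j in seq_len(J)) {
        dvj <- matrix(0, n, D)
        for (d in seq_len(D)) {
          dvj[, d] <- rowSums(db[[j]] * Uv_jd[[j]][[d]])
          duhat[[j]][, d] <- duhat[[j]][, d] +
            as.vector(db[[j]] * vprev[[j]]$v[, d])
        }
        dv_cur[[j]] <- dvj
      }
    }
  }
  duhat
}

#' Dynamic routing by agreement
#'
#' Iteratively couples lower-layer capsule predictions to upper capsules:
#' starting from zero logits, each iteration sets the couplings to the
#' per-lower-capsule softmax of the logits (over upper capsules), forms each
#' upper capsule's input as the coupling-weighted sum of predictions,
#' squashes it, and increments the logits by the scalar agreement between
#' predictions and outputs.
#'
#' @param uhat prediction array, either `n x n_low x J x D` (batch) or
#'   `n_low x J x D` (single item).
#' @param iterations number of routing iterations (>= 1; 3 by default, which
#'   suffices for stable couplings).
#' @return List with `v` (squashed upper capsules, `n x J x D`), `couplings`
#'   (`n x n_low x J`, summing to 1 over the upper index for every lower
#'   capsule), and `logits` (same shape as `couplings`).
#' @export
route_capsules <- function(uhat, iterations = 3L) {
  single <- length(dim(uhat)) == 3L
  if (single) uhat <- array(uhat, c(1L, dim(uhat)))
  if (any(!is.finite(uhat))) stop("non-finite prediction vectors in routing")
  stopifnot(iterations >= 1L)
  dms <- dim(uhat); n <- dms[1]; n_low <- dms[2]; J <- dms[3]; D <- dms[4]
  Uv_jd <- lapply(seq_len(J), function(j)
    lapply(seq_len(D), function(d) matrix(uhat[, , j, d], n, n_low)))
  rt <- .route_forward(Uv_jd, iterations, n, n_low, J, D)
  v <- array(0, c(n, J, D))
  cc <- array(0, c(n, n_low, J))
  bb <- array(0, c(n, n_low, J))
  for (j in seq_len(J)) {
    v[, j, ] <- rt$v[[j]]
    cc[, , j] <- rt$couplings[[j]]
    bb[, , j] <- rt$logits[[j]]
  }
  if (single) {
    v <- array(v, dim(v)[-1]); cc <- array(cc, dim(cc)[-1])
    bb <- array(bb, dim(bb)[-1])
  }
  list(v = v, couplings = cc, logits = bb)
}

#' Margin loss on class-capsule norms
#'
#' Per class `c`: `T_c * max(0, m_plus - ||v_c||)^2 +
#' lambda_down * (1 - T_c) * max(0, ||v_c|| - m_minus)^2`, summed over
#' classes; for a batch, the mean over items is returned.
#'
#' @param lengths capsule norms: vector of length J or an `n x J` matrix.
#' @param targets one-hot targets with the same shape.
#' @param m_plus,m_minus,lambda_down margin constants.
#' @return Scalar loss.
#' @export
#' @examples
#' margin_loss(c(0.5, 0.5), c(1, 0))  # 0.24
margin_loss <- function(lengths, targets, m_plus = 0.9, m_minus = 0.1,
                        lambda_down = 0.5) {
  if (is.null(dim(lengths))) lengths <- matrix(lengths, 1L)
  if (is.null(dim(targets))) targets <- matrix(targets, 1L)
  if (!all(dim(lengths) == dim(targets)))
    stop("lengths and targets must have matching shapes")
  if (!all(targets %in% c(0, 1)) || !all(rowSums(targets) == 1))
    stop("targets must be one-hot over the classes")
  hp <- pmax(0, m_plus - lengths)
  hm <- pmax(0, lengths - m_minus)
  mean(rowSums(targets * hp^2 + lambda_down * (1 - targets) * hm^2))
}

#' Overall training loss
#'
#' Classification (margin) loss plus `mu` times the pixel-mean squared error
#' between the input image and its reconstruction.
#'
#' @param margin margin-loss value.
#' @param image,reconstruction images of identical extent (vectors or
#'   matrices of pixels in `[0, 1]`).
#' @param mu reconstruction weight (default 4).
#' @return Scalar loss.
#' @export
#' @examples
#' overall_loss(0.24, rep(0, 4), rep(0.1, 4), mu = 4)
overall_loss <- function(margin, image, reconstruction, mu = 4) {
  if (length(image) != length(reconstruction))
    stop("image and reconstruction differ in extent (",
         length(image), " vs ", length(reconstruction), " pixels)")
  margin + mu * mean((as.numeric(image) - as.numeric(reconstruction))^2)
}

# decoder forward; C: n x digit_dim
.dec_forward <- function(params, C) {
  Z1 <- C %*% params$DW1 + rep(params$Db1, each = nrow(C))
  H1 <- relu(Z1)
  Z2 <- H1 %*% params$DW2 + rep(params$Db2, each = nrow(C))
  H2 <- relu(Z2)
  Z3 <- H2 %*% params$DW3 + rep(params$Db3, each = nrow(C))
  R <- 1 / (1 + exp(-Z3))
  list(C = C, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, R = R)
}

#' Decode a class capsule into an image
#'
#' Runs the three-layer reconstruction decoder (ReLU, ReLU, sigmoid output)
#' on a 16-D capsule.  Deterministic given the model weights.
#'
#' @param model a `capsnet_model`.
#' @param capsule a 16-component vector or an `n x 16` matrix.
#' @return Pixel matrix `n x side^2` (or a vector for a single capsule),
#'   intensities in `(0, 1)`.
#' @export
decode_capsule <- function(model, capsule) {
  single <- is.null(dim(capsule))
  C <- if (single) matrix(capsule, 1L) else as.matrix(capsule)
  if (ncol(C) != model$config$digit_dim)
    stop("capsule must have ", model$config$digit_dim, " components (got ",
         ncol(C), ")")
  R <- .dec_forward(model$params, C)$R
  if (single) as.numeric(R) else R
}

#' Forward pass to primary capsules
#'
#' Exposes the convolutional front end: first-layer ReLU feature maps and
#' the squashed primary-capsule grid.
#'
#' @param model a `capsnet_model`.
#' @param images `n x side^2` pixel matrix (or a single image vector).
#' @return List with `conv1_dim` (`c(oh, ow, filters)`), `capsules`
#'   (`n x n_low x primary_dim`, squashed), and `grid_dim`
#'   (`c(oh2, ow2, maps)`).
#' @export
capsnet_primary <- function(model, images) {
  if (is.null(dim(images))) images <- matrix(images, 1L)
  cfg <- model$config
  if (ncol(images) != cfg$side^2)
    stop("expected ", cfg$side^2, "-pixel images (", cfg$side, "x", cfg$side,
         "), got ", ncol(images), " pixels")
  g <- .capsnet_geom(cfg)
  fp <- .forward_to_primary(model$params, cfg, g, images)
  caps <- array(fp$Uv, c(fp$n, g$n_low, cfg$primary_dim))
  list(conv1_dim = c(g$ci1$oh, g$ci1$ow, cfg$conv1_filters),
       capsules = caps,
       grid_dim = c(g$ci2$oh, g$ci2$ow, cfg$primary_maps))
}

#' Full forward pass to class capsules
#'
#' @param model a `capsnet_model`.
#' @param images `n x side^2` pixel matrix (or single image vector).
#' @param chunk evaluate at most this many images per BLAS pass.
#' @return List with `capsules` (`n x J x digit_dim`), `lengths` (`n x J`)
#'   and `class` (predicted labels, longer-capsule rule; ties resolve to the
#'   first/lower class label).
#' @export
predict_capsnet <- function(model, images, chunk = 64L) {
  if (is.null(dim(images))) images <- matrix(images, 1L)
  cfg <- model$config
  g <- .capsnet_geom(cfg)
  n <- nrow(images)
  J <- cfg$n_classes; D <- cfg$digit_dim
  v <- array(0, c(n, J, D))
  for (start in seq(1L, n, by = chunk)) {
    ii <- start:min(n, start + chunk - 1L)
    fp <- .forward_to_primary(model$params, cfg, g, images[ii, , drop = FALSE])
    uhat <- .forward_uhat(model$params, cfg, g, fp$Uv, length(ii))
    rt <- .route_forward(.uhat_views(uhat, length(ii), g$n_low, D),
                         cfg$routing_iters, length(ii), g$n_low, J, D)
    for (j in seq_len(J)) v[ii, j, ] <- rt$v[[j]]
  }
  lengths <- sqrt(apply(v^2, c(1L, 2L), sum))
  cls <- cfg$classes[row_argmax_first(lengths)]
  list(capsules = v, lengths = lengths, class = cls)
}

# ---- loss + gradients -------------------------------------------------------

# label_idx: integer in 1..J per row of X
.capsnet_loss_grad <- function(params, cfg, g, X, label_idx, grads = TRUE) {
  n <- nrow(X); J <- cfg$n_classes; D <- cfg$digit_dim
  fp <- .forward_to_primary(params, cfg, g, X)
  uhat <- .forward_uhat(params, cfg, g, fp$Uv, n)
  Uv_jd <- .uhat_views(uhat, n, g$n_low, D)
  rt <- .route_forward(Uv_jd, cfg$routing_iters, n, g$n_low, J, D)
  lengths <- vapply(rt$v, function(vj) sqrt(rowSums(vj * vj)), numeric(n))
  lengths <- matrix(lengths, n, J)
  Tm <- matrix(0, n, J); Tm[cbind(seq_len(n), label_idx)] <- 1
  hp <- pmax(0, cfg$m_plus - lengths)
  hm <- pmax(0, lengths - cfg$m_minus)
  margin <- mean(rowSums(Tm * hp^2 + cfg$lambda_down * (1 - Tm) * hm^2))
  vt <- matrix(0, n, D)
  for (j in seq_len(J)) {
    pick <- label_idx == j
    if (any(pick)) vt[pick, ] <- rt$v[[j]][pick, , drop = FALSE]
  }
  dec <- .dec_forward(params, vt)
  mse_i <- rowMeans((X - dec$R)^2)
  loss <- margin + cfg$mu * mean(mse_i)
  if (!grads) return(list(loss = loss, margin = margin, lengths = lengths,
                          recon = dec$R, v = rt$v))
  np <- cfg$side^2
  # decoder backward
  dR <- (dec$R - X) * (2 * cfg$mu / (n * np))
  dZ3 <- dR * dec$R * (1 - dec$R)
  gDW3 <- crossprod(dec$H2, dZ3); gDb3 <- colSums(dZ3)
  dH2 <- tcrossprod(dZ3, params$DW3)
  dZ2 <- dH2 * (dec$Z2 > 0)
  gDW2 <- crossprod(dec$H1, dZ2); gDb2 <- colSums(dZ2)
  dH1 <- tcrossprod(dZ2, params$DW2)
  dZ1 <- dH1 * (dec$Z1 > 0)
  gDW1 <- crossprod(vt, dZ1); gDb1 <- colSums(dZ1)
  dvt <- tcrossprod(dZ1, params$DW1)
  # margin backward
  dlen <- (-2 * Tm * hp + 2 * cfg$lambda_down * (1 - Tm) * hm) / n
  lsafe <- pmax(lengths, 1e-12)
  dv <- lapply(seq_len(J), function(j) {
    dvj <- (dlen[, j] / lsafe[, j]) * rt$v[[j]]
    pick <- label_idx == j
    if (any(pick)) dvj[pick, ] <- dvj[pick, ] + dvt[pick, , drop = FALSE]
    dvj
  })
  # routing / prediction backward
  duhat <- .route_backward_core(dv, Uv_jd, rt$cache, n, g$n_low, J, D)
  rep_i <- rep(seq_len(g$n_low), each = n)
  dUv <- matrix(0, n * g$n_low, cfg$primary_dim)
  gW <- array(0, dim(params$W))
  for (j in seq_len(J)) {
    Dj <- duhat[[j]]
    for (k in seq_len(cfg$primary_dim)) {
      Wjk <- matrix(params$W[, j, , k], g$n_low, D)
      dUv[, k] <- dUv[, k] + rowSums(Dj * Wjk[rep_i, , drop = FALSE])
      gW[, j, , k] <- rowsum(Dj * fp$Uv[, k], rep_i)
    }
  }
  dM <- .squash_backward(dUv, fp$M, fp$r)
  dU <- array(dM, c(n, g$ci2$n_pos, cfg$primary_maps, cfg$primary_dim))
  dY2 <- matrix(aperm(dU, c(1L, 2L, 4L, 3L)), n * g$ci2$n_pos, g$c2)
  cb2 <- conv_backward(dY2, params$K2, fp$c2, g$ci2, g$S2)
  dX2 <- cb2$dX
  dim(dX2) <- c(n * g$ci1$n_pos, cfg$conv1_filters)
  dZc1 <- dX2 * (fp$c1$Y > 0)
  cb1 <- conv_backward(dZc1, params$K1, fp$c1, g$ci1, NULL)
  grads_out <- list(K1 = cb1$dK, bc1 = cb1$db, K2 = cb2$dK, bc2 = cb2$db,
                    W = gW, DW1 = gDW1, Db1 = gDb1, DW2 = gDW2, Db2 = gDb2,
                    DW3 = gDW3, Db3 = gDb3)
  list(loss = loss, margin = margin, lengths = lengths, grads = grads_out)
}

# ---- Adam -------------------------------------------------------------------

# flat-vector parameter handling: one Adam update over a single numeric
# vector avoids per-tensor allocation churn in the training loop
.flatten_params <- function(params) {
  skel <- lapply(params, function(p) dim(p) %||% length(p))
  list(theta = unlist(params, use.names = FALSE), skel = skel)
}

.unflatten_params <- function(theta, skel) {
  out <- vector("list", length(skel))
  names(out) <- names(skel)
  pos <- 0L
  for (nm in names(skel)) {
    d <- skel[[nm]]
    len <- prod(d)
    p <- theta[(pos + 1L):(pos + len)]
    if (length(d) > 1L) dim(p) <- d
    out[[nm]] <- p
    pos <- pos + len
  }
  out
}

.adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a capsule network end to end
#'
#' Joint training of the classification path (margin loss on capsule norms)
#' and the reconstruction path (decoder fed the *target-class* capsule, pixel
#' MSE weighted by `mu`) with Adam, minibatches of `config$batch`, for
#' `config$epochs` epochs.  Deterministic for a fixed `config$seed`.
#'
#' @param images `n x side^2` pixel matrix or `stimulus_set`.
#' @param labels class labels (must cover at least 2 classes, subset of
#'   `config$classes`).
#' @param config a [capsnet_config()] (use [scaled_capsnet_config()] for
#'   desk-scale runs).
#' @param verbose print per-epoch loss.
#' @return A trained `capsnet_model` whose `trace` holds the per-epoch mean
#'   training loss.
#' @export
train_capsnet <- function(images, labels = NULL, config = capsnet_config(),
                          verbose = FALSE) {
  if (inherits(images, "stimulus_set")) {
    labels <- labels %||% images$labels
    images <- images$images
  }
  if (length(unique(labels)) < 2L)
    stop("training requires at least 2 classes present")
  if (!all(labels %in% config$classes))
    stop("labels outside config$classes: ",
         paste(setdiff(labels, config$classes), collapse = ", "))
  label_idx <- match(labels, config$classes)
  model <- init_capsnet(config)
  g <- .capsnet_geom(config, scatter = TRUE)
  fl <- .flatten_params(model$params)
  theta <- fl$theta
  mo <- theta * 0; vo <- theta * 0; tstep <- 0L
  params <- model$params
  n <- nrow(images)
  n_batches <- length(seq(1L, n, by = config$batch))
  epoch_loss <- numeric(config$epochs)
  local_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- numeric(n_batches)
      bi <- 0L
      for (start in seq(1L, n, by = config$batch)) {
        ii <- perm[start:min(n, start + config$batch - 1L)]
        lg <- .capsnet_loss_grad(params, config, g,
                                 images[ii, , drop = FALSE], label_idx[ii])
        if (!is.finite(lg$loss))
          stop("training diverged (non-finite loss) at epoch ", ep,
               "; reduce the learning rate")
        gf <- unlist(lg$grads, use.names = FALSE)
        tstep <- tstep + 1L
        mo <- config$beta1 * mo + (1 - config$beta1) * gf
        vo <- config$beta2 * vo + (1 - config$beta2) * gf * gf
        theta <- theta - config$lr * (mo / (1 - config$beta1^tstep)) /
          (sqrt(vo / (1 - config$beta2^tstep)) + config$adam_eps)
        params <- .unflatten_params(theta, fl$skel)
        bi <- bi + 1L
        losses[bi] <- lg$loss
      }
      epoch_loss[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f", ep, config$epochs,
                        epoch_loss[ep]))
    }
  })
  model$params <- params
  model$trace <- list(loss = epoch_loss)
  model
}
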