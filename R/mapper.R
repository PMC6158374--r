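#' Mapper training configuration
#'
#' The voxel-to-capsule mapper is a three-layer fully connected network:
#' input (selected voxels) -> 256 (ReLU) -> 128 (ReLU) -> 32 (linear), the
#' 32-D output split into two 16-D halves that are each squashed to valid
#' capsules.  Trained with Adam (initial learning rate 1e-4, batch 10,
#' ~10,000 iterations) on the mean squared error between predicted and true
#' capsule features, with an L2 penalty on the first two layers' weights.
#'
#' @param hidden sizes of the two hidden layers.
#' @param lr,beta1,beta2,adam_eps Adam hyperparameters.
#' @param batch minibatch size.
#' @param iterations number of Adam steps.
#' @param l2_strength L2 penalty weight on layers 1 and 2.
#' @param standardize z-score voxel inputs with training statistics stored
#'   in the model (applied automatically at prediction time).
#' @param activation hidden activation: `"relu"` (default) or `"identity"`
#'   (diagnostic mode used by attribution checks).
#' @param eval_every record test loss every this many iterations.
#' @param seed integer seed (initialization + batch order).
#' @return A list of class `"mapper_config"`.
#' @export
mapper_config <- function(hidden = c(256L, 128L), lr = 1e-4, beta1 = 0.9,
                          beta2 = 0.999, adam_eps = 1e-8, batch = 10L,
                          iterations = 10000L, l2_strength = 1e-3,
                          standardize = TRUE, activation = c("relu", "identity"),
                          eval_every = 100L, seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(lr > 0, batch >= 1, iterations >= 0, l2_strength >= 0)
  structure(as.list(environment()), class = "mapper_config")
}

.mapper_act <- function(Z, activation) if (activation == "relu") relu(Z) else Z
.mapper_act_grad <- function(Z, activation)
  if (activation == "relu") (Z > 0) * 1 else array(1, dim(Z))

.init_mapper <- function(n_in, cfg, n_caps = 2L, digit_dim = 16L) {
  local_seed(cfg$seed, {
    he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
    list(W1 = he(n_in, cfg$hidden[1]), b1 = numeric(cfg$hidden[1]),
         W2 = he(cfg$hidden[1], cfg$hidden[2]), b2 = numeric(cfg$hidden[2]),
         W3 = matrix(stats::rnorm(cfg$hidden[2] * n_caps * digit_dim, 0,
                                  sqrt(1 / cfg$hidden[2])),
                     cfg$hidden[2], n_caps * digit_dim),
         b3 = numeric(n_caps * digit_dim))
  })
}

# forward to the pre-squash 32-D output; X already standardized
.mapper_forward <- function(params, X, activation) {
  Z1 <- X %*% params$W1 + rep(params$b1, each = nrow(X))
  H1 <- .mapper_act(Z1, activation)
  Z2 <- H1 %*% params$W2 + rep(params$b2, each = nrow(X))
  H2 <- .mapper_act(Z2, activation)
  Z3 <- H2 %*% params$W3 + rep(params$b3, each = nrow(X))
  list(Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, Z3 = Z3)
}

# split 32-D rows into two squashed 16-D capsules: n x 2 x 16
.split_squash <- function(Z3, digit_dim = 16L) {
  n <- nrow(Z3); J <- ncol(Z3) / digit_dim
  v <- array(0, c(n, J, digit_dim))
  for (j in seq_len(J)) {
    cols <- ((j - 1L) * digit_dim + 1L):(j * digit_dim)
    v[, j, ] <- squash(Z3[, cols, drop = FALSE])
  }
  v
}

# loss = mean((pred - true)^2) over all n*J*D entries + l2 * (||W1||^2 + ||W2||^2)
.mapper_loss_grad <- function(params, X, Ytrue, cfg, digit_dim = 16L,
                              grads = TRUE) {
  n <- nrow(X); J <- dim(Ytrue)[2]
  fw <- .mapper_forward(params, X, cfg$activation)
  pred <- .split_squash(fw$Z3, digit_dim)
  err <- pred - Ytrue
  mse <- mean(err^2)
  loss <- mse + cfg$l2_strength * (sum(params$W1^2) + sum(params$W2^2))
  if (!grads) return(list(loss = loss, mse = mse, pred = pred))
  dZ3 <- matrix(0, n, J * digit_dim)
  scale <- 2 / length(err)
  for (j in seq_len(J)) {
    cols <- ((j - 1L) * digit_dim + 1L):(j * digit_dim)
    Sj <- fw$Z3[, cols, drop = FALSE]
    r <- sqrt(rowSums(Sj * Sj))
    dZ3[, cols] <- .squash_backward(scale * matrix(err[, j, ], n, digit_dim),
                                    Sj, r)
  }
  gW3 <- crossprod(fw$H2, dZ3); gb3 <- colSums(dZ3)
  dH2 <- tcrossprod(dZ3, params$W3)
  dZ2 <- dH2 * .mapper_act_grad(fw$Z2, cfg$activation)
  gW2 <- crossprod(fw$H1, dZ2) + 2 * cfg$l2_strength * params$W2
  gb2 <- colSums(dZ2)
  dH1 <- tcrossprod(dZ2, params$W2)
  dZ1 <- dH1 * .mapper_act_grad(fw$Z1, cfg$activation)
  gW1 <- crossprod(X, dZ1) + 2 * cfg$l2_strength * params$W1
  gb1 <- colSums(dZ1)
  list(loss = loss, mse = mse,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3,
                    b3 = gb3))
}

#' Train the voxel-to-capsule mapper
#'
#' Minimizes the mean squared error between the mapper's two squashed 16-D
#' output capsules and the true capsule features (from a frozen capsule
#' network), plus L2 penalties on the first two layers, with Adam.  The
#' capsule-network weights are never touched.  With `iterations = 0` the
#' initialized model is returned unchanged.
#'
#' @param voxels `n x V_sel` matrix of (selected) voxel responses.
#' @param true_capsules `n x 2 x 16` array of target capsules (class order:
#'   first capsule = lower class label).
#' @param config a [mapper_config()].
#' @param test_voxels,test_capsules optional held-out set; its MSE is
#'   recorded every `config$eval_every` iterations.
#' @return An object of class `"mapper_model"`: `params`, `config`,
#'   `center`/`scale` (input standardization), `trace` (data frame of
#'   iteration, train loss, train MSE, and test MSE when available).
#' @export
train_mapper <- function(voxels, true_capsules, config = mapper_config(),
                         test_voxels = NULL, test_capsules = NULL) {
  voxels <- as.matrix(voxels)
  n <- nrow(voxels)
  if (length(dim(true_capsules)) != 3L || dim(true_capsules)[1] != n)
    stop("true_capsules must be an n x J x 16 array aligned with voxels")
  if (n < config$batch)
    stop("n = ", n, " is smaller than the batch size (", config$batch, ")")
  digit_dim <- dim(true_capsules)[3]
  if (config$standardize) {
    center <- colMeans(voxels)
    scl <- apply(voxels, 2L, stats::sd)
    scl[scl < 1e-12] <- 1
  } else {
    center <- rep(0, ncol(voxels)); scl <- rep(1, ncol(voxels))
  }
  X <- sweep(sweep(voxels, 2L, center), 2L, scl, "/")
  params <- .init_mapper(ncol(X), config, dim(true_capsules)[2], digit_dim)
  st <- .adam_init(params)
  trace <- list()
  has_test <- !is.null(test_voxels)
  if (has_test) {
    Xt <- sweep(sweep(as.matrix(test_voxels), 2L, center), 2L, scl, "/")
  }
  local_seed(config$seed + 1L, {
    it <- 0L
    while (it < config$iterations) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = config$batch)) {
        if (it >= config$iterations) break
        ii <- perm[start:min(n, start + config$batch - 1L)]
        lg <- .mapper_loss_grad(params, X[ii, , drop = FALSE],
                                true_capsules[ii, , , drop = FALSE], config,
                                digit_dim)
        if (!is.finite(lg$loss))
          stop("mapper training diverged (non-finite loss) at iteration ", it)
        up <- .adam_step(params, lg$grads, st, config$lr, config$beta1,
                         config$beta2, config$adam_eps)
        params <- up$params; st <- up$state
        it <- it + 1L
        if (it %% config$eval_every == 0L || it == config$iterations) {
          test_mse <- NA_real_
          if (has_test)
            test_mse <- .mapper_loss_grad(params, Xt, test_capsules, config,
                                          digit_dim, grads = FALSE)$mse
          trace[[length(trace) + 1L]] <-
            data.frame(iteration = it, train_loss = lg$loss, train_mse = lg$mse,
                       test_mse = test_mse)
        }
      }
    }
  })
  structure(list(params = params, config = config, center = center,
                 scale = scl, digit_dim = digit_dim,
                 trace = do.call(rbind, trace)),
            class = "mapper_model")
}

#' @export
print.mapper_model <- function(x, ...) {
  cat(sprintf("<mapper_model> %d -> %d -> %d -> %d (two squashed %d-D capsules)\n",
              nrow(x$params$W1), ncol(x$params$W1), ncol(x$params$W2),
              ncol(x$params$W3), x$digit_dim))
  if (!is.null(x$trace) && nrow(x$trace))
    cat(sprintf("  final train MSE %.5f\n", utils::tail(x$trace$train_mse, 1)))
  invisible(x)
}

#' Predict capsules from voxel responses
#'
#' Applies the stored input standardization and the three-layer network;
#' the 32-D output is split into two 16-D halves and each is squashed, so
#' both predicted capsule norms are below 1.  Capsule 1 corresponds to the
#' lower class label, capsule 2 to the higher (fixed by the capsule-network
#' class order used in training).
#'
#' @param model a trained [train_mapper()] model.
#' @param voxels a single voxel vector or an `n x V_sel` matrix.
#' @return `2 x 16` matrix for a single input, else an `n x 2 x 16` array.
#' @export
predict_capsules <- function(model, voxels) {
  single <- is.null(dim(voxels))
  X <- if (single) matrix(voxels, 1L) else as.matrix(voxels)
  if (ncol(X) != nrow(model$params$W1))
    stop("input has ", ncol(X), " voxels but the mapper expects ",
         nrow(model$params$W1))
  X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  fw <- .mapper_forward(model$params, X, model$config$activation)
  v <- .split_squash(fw$Z3, model$digit_dim)
  if (single) matrix(v[1L, , ], dim(v)[2], dim(v)[3]) else v
}
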