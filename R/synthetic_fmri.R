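#' Generate synthetic voxel responses from capsule features
#'
#' Inverts the linear encoding model the selection stage assumes: each
#' *informative* voxel responds as a linear function of the 16 longer-capsule
#' features plus an intercept and i.i.d. Gaussian noise; the remaining voxels
#' are pure noise.  Ground truth (encoding weights, intercepts, informative
#' indices, noise scales) is recorded so parameter recovery is testable.
#'
#' Noise calibration targets the *in-sample* coefficient of determination of
#' an ordinary-least-squares refit with 16 features + intercept: because the
#' in-sample R^2 of an OLS fit is biased upward by roughly
#' `(1 - rho) * p / (n - 1)` (p = 16 features), the generator solves for the
#' population fraction `rho = (snr_r2 - p/(n-1)) / (1 - p/(n-1))` and sets the
#' noise variance to `var(signal) * (1 - rho) / rho`, so that the mean
#' in-sample R^2 of informative voxels concentrates on `snr_r2`.
#'
#' @param true_capsules `n x 16` matrix of generating features (typically the
#'   longer-capsule features of a trained capsule network).
#' @param n_voxels total number of voxels V.
#' @param n_informative number of voxels carrying signal (`<= n_voxels`).
#' @param snr_r2 target explained-variance fraction in `(0, 1]`; `1` means
#'   noiseless (exact linear responses).
#' @param seed integer RNG seed.
#' @param images optional stimulus images to carry along in the study.
#' @param labels optional class labels to carry along.
#' @return An object of class `"synthetic_study"`: list with `voxels`
#'   (`n x n_voxels`), `true_capsules`, `encoding_weights` (`16 x n_voxels`,
#'   all-zero columns for uninformative voxels), `intercepts`, `informative_idx`,
#'   `noise_sd` (per voxel), `snr_r2`, `seed`, and optionally `images`,
#'   `labels`.
#' @export
generate_fmri <- function(true_capsules, n_voxels, n_informative, snr_r2,
                          seed, images = NULL, labels = NULL) {
  true_capsules <- as.matrix(true_capsules)
  n <- nrow(true_capsules)
  p <- ncol(true_capsules)
  if (p != 16L) stop("true_capsules must have 16 columns (got ", p, ")")
  if (n < 17L)
    stop("n = ", n, " stimuli cannot identify a 16-feature + intercept ",
         "regression downstream; need n >= 17")
  stopifnot(n_informative <= n_voxels, n_informative >= 0)
  if (!(snr_r2 > 0 && snr_r2 <= 1)) stop("snr_r2 must be in (0, 1]")
  vars <- apply(true_capsules, 2L, stats::var)
  if (any(vars < 1e-12))
    warning("true_capsules has zero-variance feature(s): ",
            paste(which(vars < 1e-12), collapse = ", "))
  # degrees-of-freedom-corrected calibration (see Details)
  if (snr_r2 < 1) {
    if (n < 18L)
      stop("noise calibration needs n >= 18 when snr_r2 < 1")
    rho <- (snr_r2 - p / (n - 1)) / (1 - p / (n - 1))
    if (rho <= 0)
      stop("snr_r2 = ", snr_r2, " is below the null in-sample R^2 (~",
           round(p / (n - 1), 3), ") at n = ", n, "; increase snr_r2 or n")
  } else rho <- 1
  local_seed(seed, {
    W <- matrix(0, p, n_voxels)
    intercepts <- stats::rnorm(n_voxels, 0, 0.5)
    noise_sd <- rep(1, n_voxels)          # null voxels: unit Gaussian noise
    informative_idx <- if (n_informative > 0)
      sort(sample.int(n_voxels, n_informative)) else integer(0)
    if (n_informative > 0) {
      W[, informative_idx] <- stats::rnorm(p * n_informative)
      signal <- true_capsules %*% W[, informative_idx, drop = FALSE]
      sig_var <- apply(signal, 2L, stats::var)
      noise_sd[informative_idx] <- if (rho < 1)
        sqrt(sig_var * (1 - rho) / rho) else 0
    }
    voxels <- true_capsules %*% W +
      matrix(intercepts, n, n_voxels, byrow = TRUE) +
      matrix(stats::rnorm(n * n_voxels), n, n_voxels) *
        matrix(noise_sd, n, n_voxels, byrow = TRUE)
    structure(list(voxels = voxels, true_capsules = true_capsules,
                   encoding_weights = W, intercepts = intercepts,
                   informative_idx = informative_idx, noise_sd = noise_sd,
                   snr_r2 = snr_r2, seed = seed,
                   images = images, labels = labels),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_study> %d stimuli x %d voxels ",
                     "(%d informative, target R^2 %.2f)\n"),
              nrow(x$voxels), ncol(x$voxels), length(x$informative_idx),
              x$snr_r2))
  invisible(x)
}

# Surrogate 16-D "capsule" features built from the true glyph parameters.
# Used by the CLI simulate stage, which must be runnable before any capsule
# network exists: the 7 glyph parameters (class sign, orientation, scale,
# stroke width, loop radius, dx, dy) are standardized and embedded through a
# fixed random rotation into 16 dimensions.
surrogate_features <- function(stimuli, seed = 1L) {
  p <- stimuli$params
  base <- cbind(ifelse(p$class == 6, 1, -1), scale(p$orientation),
                scale(p$scale), scale(p$stroke_width), scale(p$circle_radius),
                scale(p$dx), scale(p$dy))
  base[is.nan(base)] <- 0
  local_seed(seed, {
    proj <- matrix(stats::rnorm(ncol(base) * 16L), ncol(base), 16L)
    base %*% proj / sqrt(ncol(base))
  })
}
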