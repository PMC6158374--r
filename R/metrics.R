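#' Image reconstruction metrics
#'
#' `mse_metric` is the pixel-mean squared difference; `pcc_metric` is the
#' Pearson correlation of the flattened pixel vectors; `ssim_metric` is the
#' structural similarity index with the canonical constants (11x11 Gaussian
#' window, sigma = 1.5, K1 = 0.01, K2 = 0.03, dynamic range 1), averaged
#' over the valid local map.
#'
#' @param a,b images of identical extent: vectors of `side^2` pixels or
#'   `side x side` matrices, intensities on `[0, 1]`.
#' @return A scalar.
#' @name reconstruction_metrics
NULL

#' @rdname reconstruction_metrics
#' @export
mse_metric <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("images differ in extent")
  mean((a - b)^2)
}

#' @rdname reconstruction_metrics
#' @export
pcc_metric <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("images differ in extent")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("Pearson pixel correlation is undefined for a constant image; ",
         "compare non-constant images or use mse_metric()")
  stats::cor(a, b)
}

# separable valid-mode Gaussian filtering of a square image
.gauss_filter <- function(img, w) {
  m <- apply(img, 2L, function(col) as.numeric(stats::filter(col, w)))
  m <- m[!is.na(m[, 1]), , drop = FALSE]
  m <- t(apply(m, 1L, function(row) as.numeric(stats::filter(row, w))))
  m[, !is.na(m[1, ]), drop = FALSE]
}

#' @rdname reconstruction_metrics
#' @param window SSIM window size (odd; default 11).
#' @param sigma Gaussian window s.d. (default 1.5).
#' @param k1,k2 stabilization constants (defaults 0.01, 0.03).
#' @param dynamic_range value range of the images (default 1).
#' @export
ssim_metric <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01,
                        k2 = 0.03, dynamic_range = 1) {
  side_a <- if (is.matrix(a)) nrow(a) else as.integer(sqrt(length(a)))
  side_b <- if (is.matrix(b)) nrow(b) else as.integer(sqrt(length(b)))
  if (length(a) != length(b)) stop("images differ in extent")
  A <- matrix(as.numeric(a), side_a)
  B <- matrix(as.numeric(b), side_b)
  if (nrow(A) < window || ncol(A) < window)
    stop("image (", nrow(A), "x", ncol(A), ") is smaller than the SSIM ",
         "window (", window, ")")
  half <- (window - 1L) / 2
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- w / sum(w)
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  mu_a <- .gauss_filter(A, w)
  mu_b <- .gauss_filter(B, w)
  var_a <- .gauss_filter(A * A, w) - mu_a^2
  var_b <- .gauss_filter(B * B, w) - mu_b^2
  cov_ab <- .gauss_filter(A * B, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2)
  mean(num / den)
}
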