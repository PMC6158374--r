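#' Features of the longer class capsule
#'
#' At inference the class capsule with the larger norm carries the stimulus
#' description; its 16 components are the features used for voxel encoding.
#' Exact ties resolve to the first capsule (the lower class label).
#'
#' @param capsules a `J x 16` matrix of class capsules (rows in class
#'   order), or an `n x J x 16` array for a batch.
#' @return A 16-vector, or an `n x 16` matrix (with attribute `"which"`
#'   giving the chosen capsule index per item).
#' @export
longer_capsule_features <- function(capsules) {
  if (is.matrix(capsules)) {
    norms <- sqrt(rowSums(capsules^2))
    which_j <- which.max(norms)  # which.max takes the first of exact ties
    out <- capsules[which_j, ]
    attr(out, "which") <- which_j
    return(out)
  }
  stopifnot(length(dim(capsules)) == 3L)
  n <- dim(capsules)[1]; J <- dim(capsules)[2]; D <- dim(capsules)[3]
  norms <- sqrt(apply(capsules^2, c(1L, 2L), sum))
  which_j <- row_argmax_first(norms)
  out <- matrix(0, n, D)
  for (j in seq_len(J)) {
    pick <- which_j == j
    if (any(pick)) out[pick, ] <- capsules[pick, j, , drop = FALSE]
  }
  attr(out, "which") <- which_j
  out
}

#' Fit per-voxel linear encoding models
#'
#' Ordinary least squares of each voxel's response on the 16 capsule
#' features plus an intercept, with the in-sample coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot` per voxel.  A constant voxel
#' (zero variance) gets `R^2 = 0` with a warning.
#'
#' @param features `n x 16` matrix of (longer-capsule) features.
#' @param voxels `n x V` matrix of voxel responses.
#' @return An object of class `"encoding_fit"`: list with `weights`
#'   (`17 x V`; intercept first), `r_squared` (length V), `n`, `df_model`.
#' @export
fit_voxel_encoding <- function(features, voxels) {
  features <- as.matrix(features); voxels <- as.matrix(voxels)
  n <- nrow(features); p <- ncol(features)
  if (nrow(voxels) != n) stop("features and voxels disagree on n")
  if (n <= p + 1L)
    stop("n = ", n, " stimuli cannot identify ", p,
         " features + intercept; need n > ", p + 1L)
  X <- cbind(1, features)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning("rank-deficient feature design (rank ", qx$rank, " < ",
            ncol(X), "); minimum-norm solution used")
  coefs <- qr.coef(qx, voxels)
  coefs[is.na(coefs)] <- 0
  fitted <- X %*% coefs
  res <- voxels - fitted
  ss_res <- colSums(res^2)
  ss_tot <- colSums(sweep(voxels, 2L, colMeans(voxels))^2)
  r2 <- numeric(ncol(voxels))
  const <- ss_tot < 1e-12
  if (any(const)) {
    warning(sum(const), " constant voxel(s); their R^2 is defined as 0")
    r2[const] <- 0
  }
  r2[!const] <- 1 - ss_res[!const] / ss_tot[!const]
  structure(list(weights = coefs, r_squared = r2, n = n, df_model = p + 1L),
            class = "encoding_fit")
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("<encoding_fit> %d voxels, n = %d; R^2 median %.3f, max %.3f\n",
              length(x$r_squared), x$n, stats::median(x$r_squared),
              max(x$r_squared)))
  invisible(x)
}

#' Select the top-k voxels by encoding R-squared
#'
#' Ranks voxels by in-sample R^2 (descending), breaking exact ties by
#' ascending voxel index, and retains the top `k`.
#'
#' @param fit an [fit_voxel_encoding()] result.
#' @param k number of voxels to retain (default 100).
#' @return An object of class `"voxel_selection"`: list with `ranked_indices`
#'   (all V voxels, best first), `selected` (the top `k`, ascending index),
#'   `k`, `mask` (logical length V), `r_squared` of the selected voxels.
#' @export
select_top_k <- function(fit, k = 100L) {
  V <- length(fit$r_squared)
  if (k > V) stop("k = ", k, " exceeds the number of voxels (", V, ")")
  ranked <- order(-fit$r_squared, seq_len(V))
  selected <- sort(ranked[seq_len(k)])
  mask <- logical(V); mask[selected] <- TRUE
  structure(list(ranked_indices = ranked, selected = selected, k = k,
                 mask = mask, r_squared = fit$r_squared[selected]),
            class = "voxel_selection")
}

#' @export
print.voxel_selection <- function(x, ...) {
  cat(sprintf("<voxel_selection> %d of %d voxels; selected R^2 in [%.3f, %.3f]\n",
              x$k, length(x$mask), min(x$r_squared), max(x$r_squared)))
  invisible(x)
}

#' Cross-validated encoding performance of a voxel set
#'
#' For each voxel, out-of-fold predictions of the linear encoding model are
#' pooled over a k-fold split and correlated (Pearson) with the observed
#' responses; the mean correlation over the voxel set is returned.  Voxels
#' whose out-of-fold prediction is constant are excluded and counted.
#'
#' @param features `n x 16` feature matrix.
#' @param voxels `n x V` voxel responses.
#' @param selection a [select_top_k()] result, or an integer vector of voxel
#'   indices; `NULL` evaluates all voxels.
#' @param folds number of folds (default 10) or a precomputed fold vector
#'   from [split_folds()].
#' @param seed seed for the fold split (ignored when `folds` is a vector).
#' @param labels optional class labels for stratified folds.
#' @return List with `mean_correlation`, `per_voxel` (named by voxel index),
#'   `n_undefined`, `fold` (the fold vector).
#' @export
evaluate_encoding <- function(features, voxels, selection = NULL, folds = 10L,
                              seed = 1L, labels = NULL) {
  features <- as.matrix(features); voxels <- as.matrix(voxels)
  n <- nrow(features)
  idx <- if (is.null(selection)) seq_len(ncol(voxels))
         else if (inherits(selection, "voxel_selection")) selection$selected
         else as.integer(selection)
  Y <- voxels[, idx, drop = FALSE]
  fold <- if (length(folds) > 1L) folds else split_folds(n, folds, labels, seed)
  pred <- matrix(NA_real_, n, ncol(Y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    X <- cbind(1, features)
    co <- qr.coef(qr(X[tr, , drop = FALSE]), Y[tr, , drop = FALSE])
    co[is.na(co)] <- 0
    pred[!tr, ] <- X[!tr, , drop = FALSE] %*% co
  }
  sds <- apply(pred, 2L, stats::sd)
  ok <- sds > 1e-12 & apply(Y, 2L, stats::sd) > 1e-12
  per_voxel <- rep(NA_real_, ncol(Y))
  if (any(ok))
    per_voxel[ok] <- vapply(which(ok), function(j) stats::cor(pred[, j], Y[, j]),
                            numeric(1))
  names(per_voxel) <- idx
  list(mean_correlation = mean(per_voxel[ok]),
       per_voxel = per_voxel, n_undefined = sum(!ok), fold = fold)
}
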