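#' Capsule-dimension perturbation sweep
#'
#' Decodes a family of images obtained by adding each offset in `deltas` to
#' one dimension of a 16-D capsule, holding the others fixed — the probe
#' used to attach interpretable meaning (orientation, bend, stroke width,
#' ...) to individual capsule dimensions.  The `delta = 0` entry equals the
#' unperturbed reconstruction exactly; the input capsule is not modified.
#'
#' @param capsule 16-component capsule vector (from a trained model for
#'   meaningful output).
#' @param dim_index dimension to perturb, in `1..16`.
#' @param deltas ordered numeric offsets (default `-0.5` to `+0.5` in steps
#'   of 0.1).
#' @param capsnet trained `capsnet_model` providing the decoder.
#' @param labels optional free-text label for the dimension (user-assigned;
#'   the package computes no semantics).
#' @return An object of class `"perturbation_sweep"`: `deltas`, `images`
#'   (`length(deltas) x side^2`, rows in delta order), `dim_index`, `label`.
#' @export
perturb_dimension <- function(capsule, dim_index, deltas = seq(-0.5, 0.5, 0.1),
                              capsnet, labels = NULL) {
  capsule <- as.numeric(capsule)
  D <- capsnet$config$digit_dim
  if (length(capsule) != D)
    stop("capsule must have ", D, " components")
  if (dim_index < 1L || dim_index > D)
    stop("dim_index must be in 1..", D, " (got ", dim_index, ")")
  C <- matrix(capsule, length(deltas), D, byrow = TRUE)
  C[, dim_index] <- C[, dim_index] + deltas
  # decode row by row so the delta = 0 frame is bit-identical to a plain
  # decode_capsule() call (batched BLAS sums in a different order)
  images <- t(vapply(seq_len(nrow(C)),
                     function(i) decode_capsule(capsnet, C[i, ]),
                     numeric(capsnet$config$side^2)))
  structure(list(deltas = deltas, images = images,
                 dim_index = dim_index, label = labels),
            class = "perturbation_sweep")
}

#' @export
print.perturbation_sweep <- function(x, ...) {
  cat(sprintf("<perturbation_sweep> dimension %d%s, %d deltas in [%g, %g]\n",
              x$dim_index,
              if (!is.null(x$label)) paste0(" ('", x$label, "')") else "",
              length(x$deltas), min(x$deltas), max(x$deltas)))
  invisible(x)
}

#' Gradient-based voxel-to-feature attribution
#'
#' Computes the Jacobian of the mapper's 32-D pre-squash output (two 16-D
#' capsules) with respect to its voxel inputs by backpropagation, evaluated
#' at a reference input; entry `(v, d)` of the returned map is
#' `|d output_d / d voxel_v|`.  With several reference inputs the magnitude
#' maps are averaged.  This is a gradient sensitivity report, not a causal
#' claim about voxels.
#'
#' @param mapper trained `mapper_model`.
#' @param voxel_input reference input: a single selected-voxel vector or a
#'   matrix of rows to average over (e.g. the training set; its column mean
#'   is the conventional single reference).
#' @param signed return the signed Jacobian instead of magnitudes (only for
#'   a single reference input).
#' @param raw_units take gradients with respect to the raw voxel scale,
#'   chaining through the mapper's input standardization (default TRUE).
#' @return An `n_voxels x 32` matrix of class `"attribution_map"`
#'   (columns 1-16: capsule of the lower class; 17-32: higher class).
#' @export
attribute_voxels <- function(mapper, voxel_input, signed = FALSE,
                             raw_units = TRUE) {
  X <- if (is.null(dim(voxel_input))) matrix(voxel_input, 1L)
       else as.matrix(voxel_input)
  if (ncol(X) != nrow(mapper$params$W1))
    stop("voxel_input has ", ncol(X), " voxels but the mapper expects ",
         nrow(mapper$params$W1))
  if (signed && nrow(X) > 1L)
    stop("signed Jacobian is defined for a single reference input")
  Xs <- sweep(sweep(X, 2L, mapper$center), 2L, mapper$scale, "/")
  acc <- NULL
  for (i in seq_len(nrow(Xs))) {
    fw <- .mapper_forward(mapper$params, Xs[i, , drop = FALSE],
                          mapper$config$activation)
    m1 <- as.numeric(.mapper_act_grad(fw$Z1, mapper$config$activation))
    m2 <- as.numeric(.mapper_act_grad(fw$Z2, mapper$config$activation))
    J <- mapper$params$W1 %*% (m1 * (mapper$params$W2 %*%
                                       (m2 * mapper$params$W3)))
    if (raw_units) J <- J / mapper$scale
    acc <- if (is.null(acc)) (if (signed) J else abs(J))
           else acc + abs(J)
  }
  out <- acc / nrow(Xs)
  structure(out, class = c("attribution_map", class(out)))
}

#' Normalize an attribution map for display
#'
#' Per-dimension max scaling (each column divided by its maximum absolute
#' value); raw values should be retained for any quantitative use.
#'
#' @param map an [attribute_voxels()] result.
#' @return Matrix of the same shape with columns scaled to max 1.
#' @export
normalize_attribution <- function(map) {
  mx <- apply(abs(map), 2L, max)
  mx[mx < 1e-300] <- 1
  sweep(unclass(map), 2L, mx, "/")
}
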