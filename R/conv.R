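# Valid-mode convolution via im2col gather + one BLAS matmul, with the
# matching col2im scatter expressed as a sparse-matrix product for the
# backward pass.  Layouts (all column-major flattening):
#   input  X: n x (h*w*ch), per-image flat index = r + (c-1)*h + (k-1)*h*w
#   patches Xcol: (n*n_pos) x (ksize^2*ch), row index = b + (p-1)*n
#   output Y: (n*n_pos) x n_filters

# Precompute the gather index for a valid convolution.
conv_index <- function(h, w, ch, ksize, stride) {
  oh <- (h - ksize) %/% stride + 1L
  ow <- (w - ksize) %/% stride + 1L
  n_pos <- oh * ow
  orig_r <- (seq_len(oh) - 1L) * stride + 1L
  orig_c <- (seq_len(ow) - 1L) * stride + 1L
  # patch element q iterates (dr, dc, k) with dr fastest, matching the
  # kernel-matrix row order
  idx <- matrix(0L, n_pos, ksize * ksize * ch)
  q <- 0L
  for (k in seq_len(ch)) for (dc in 0:(ksize - 1L)) for (dr in 0:(ksize - 1L)) {
    q <- q + 1L
    rr <- rep(orig_r + dr, times = ow)
    cc <- rep(orig_c + dc, each = oh)
    idx[, q] <- rr + (cc - 1L) * h + (k - 1L) * h * w
  }
  list(idx = idx, oh = oh, ow = ow, n_pos = n_pos, in_len = h * w * ch,
       patch_len = ncol(idx))
}

# Flat gather index for a given batch size n: Xcol = matrix(X[G], n*n_pos, patch)
# where X is used as its underlying vector (n x in_len, column-major).
conv_gather_index <- function(ci, n) {
  base <- ci$idx[rep(seq_len(ci$n_pos), each = n), , drop = FALSE]
  matrix(rep(seq_len(n), times = ci$n_pos) + (base - 1L) * n,
         n * ci$n_pos, ci$patch_len)
}

# 0/1 scatter matrix S with dims (n_pos*patch_len) x in_len so that the
# gather A[b, (p,q)] = X[b, idx[p,q]] has adjoint dX = dA %*% S.
conv_scatter <- function(ci) {
  av <- as.vector(ci$idx)
  methods::as(Matrix::sparseMatrix(i = seq_along(av), j = av, x = 1,
                                   dims = c(length(av), ci$in_len)),
              "CsparseMatrix")
}

# X: n x in_len; K: patch_len x n_filters; bias: n_filters; G from
# conv_gather_index for this batch size.
conv_forward <- function(X, K, bias, ci, G) {
  n <- nrow(X)
  Xcol <- matrix(X[G], n * ci$n_pos, ci$patch_len)
  Y <- Xcol %*% K
  Y <- Y + rep(bias, each = nrow(Y))
  list(Y = Y, Xcol = Xcol, n = n)
}

# dY: (n*n_pos) x n_filters -> gradients; S from conv_scatter (NULL to skip dX)
conv_backward <- function(dY, K, cache, ci, S = NULL) {
  dK <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dX <- NULL
  if (!is.null(S)) {
    dXcol <- tcrossprod(dY, K)                      # (n*n_pos) x patch_len
    dA <- matrix(dXcol, cache$n, ci$n_pos * ci$patch_len)
    dX <- as.matrix(dA %*% S)
  }
  list(dK = dK, db = db, dX = dX)
}
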