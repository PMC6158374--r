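#' Cross-validation fold assignment
#'
#' Partitions `n` items into `k` disjoint, exhaustive folds, stratified by
#' class when `labels` are supplied (each fold receives a near-equal share of
#' each class; with 50/50 classes and `n = 100`, `k = 10`, every fold holds
#' exactly 5 of each).  Deterministic for a fixed `seed`.
#'
#' @param n number of items.
#' @param k number of folds (`k <= n`).
#' @param labels optional class labels of length `n` for stratification.
#' @param seed integer RNG seed.
#' @return Integer vector of length `n` with fold ids in `1..k`.
#' @export
#' @examples
#' f <- split_folds(100, 10, labels = rep(c(6, 9), 50), seed = 1)
#' table(f)
split_folds <- function(n, k, labels = NULL, seed = 1L) {
  stopifnot(n >= 1, k >= 1)
  if (k > n) stop("k (", k, ") must not exceed n (", n, ")")
  if (!is.null(labels) && length(labels) != n)
    stop("labels must have length n")
  local_seed(seed, {
    fold <- integer(n)
    if (is.null(labels)) {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    } else {
      # deal each class's shuffled indices round-robin, rotating the starting
      # fold between classes so overall fold sizes stay balanced
      offset <- 0L
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
        offset <- (offset + length(idx)) %% k
      }
    }
    fold
  })
}
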