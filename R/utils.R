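#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# argmax with first-wins tie break (ties resolve to the lower class label)
which_max_first <- function(x) which.max(x)

row_argmax_first <- function(m) {
  apply(m, 1L, which.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_image_vec <- function(x, side = 28L, what = "image") {
  if (length(x) != side * side)
    stop(sprintf("%s must have %d pixels (got %d)", what, side * side, length(x)),
         call. = FALSE)
  invisible(x)
}

# Deterministic 64-bit-ish FNV-1a over a character scalar; returned as hex.
# Used for config/artifact provenance hashes (no hashing package available).
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  # work in two 16-bit halves to stay in double-precision-exact integer range
  h <- 0x811c9dc5
  p <- 16777619
  for (b in bytes) {
    h <- (h - h %% 256) + bitwXor(h %% 256, b)  # xor touches the low byte only
    # 32-bit modular multiply in exact double arithmetic (split 16-bit halves)
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# mean squared error helpers used across modules
.sq <- function(x) x * x
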