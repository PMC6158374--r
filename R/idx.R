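#' Read an IDX (MNIST-style) image or label file
#'
#' Parses the standard IDX container: magic bytes `0 0 <type> <ndim>`,
#' big-endian 32-bit dimension sizes, then the payload.  Unsigned-byte image
#' archives (`ndim = 3`) are returned as a `stimulus_set`-compatible matrix
#' with intensities scaled to `[0, 1]`; unsigned-byte label archives
#' (`ndim = 1`) as an integer vector.
#'
#' @param path file path.
#' @return For image files, a list of class `"stimulus_set"` with `images`
#'   (`n x h*w` matrix, each image stored column-major) and `side`; for label
#'   files, an integer vector.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L || magic[1] != 0L || magic[2] != 0L)
    stop("not an IDX file: bad magic bytes at offset 0 in '", path, "'")
  type <- magic[3]; ndim <- magic[4]
  if (type != 0x08)
    stop("unsupported IDX element type 0x", sprintf("%02x", type),
         " at offset 2 (only unsigned byte, 0x08, is supported)")
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (length(dims) < ndim)
    stop("truncated IDX header: expected ", ndim, " dimension sizes at offset 4")
  n_total <- prod(dims)
  payload <- readBin(con, "integer", n = n_total, size = 1L, signed = FALSE)
  if (length(payload) < n_total)
    stop("truncated IDX payload: header at offset 4 promises ", n_total,
         " bytes, found ", length(payload), " (payload starts at offset ",
         4L + 4L * ndim, ")")
  if (ndim == 1L) return(as.integer(payload))
  if (ndim != 3L)
    stop("unsupported IDX rank ", ndim, " (expected 1 for labels or 3 for images)")
  n <- dims[1]; h <- dims[2]; w <- dims[3]
  if (h != w) stop("non-square IDX images (", h, "x", w, ") are not supported")
  images <- matrix(0, n, h * w)
  for (i in seq_len(n)) {
    # IDX stores each image row-major; internal layout is column-major
    img <- matrix(payload[((i - 1) * h * w + 1):(i * h * w)] / 255,
                  nrow = h, byrow = TRUE)
    images[i, ] <- as.vector(img)
  }
  structure(list(images = images, labels = NULL, side = h),
            class = "stimulus_set")
}

#' Write images (or labels) to an IDX file
#'
#' Images are quantized to 8-bit (`round(p * 255)`), the quantization the IDX
#' unsigned-byte format imposes; a write-then-read round trip reproduces the
#' quantized intensities exactly.
#'
#' @param x a `stimulus_set`, an image matrix (rows = images, each row a
#'   column-major square image), or an integer label vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.numeric(x) && is.null(dim(x))) {  # labels
    writeBin(as.raw(c(0, 0, 0x08, 1)), con)
    writeBin(as.integer(length(x)), con, size = 4L, endian = "big")
    writeBin(as.raw(as.integer(x)), con)
    return(invisible(path))
  }
  images <- if (inherits(x, "stimulus_set")) x$images else x
  side <- as.integer(sqrt(ncol(images)))
  writeBin(as.raw(c(0, 0, 0x08, 3)), con)
  writeBin(as.integer(c(nrow(images), side, side)), con, size = 4L,
           endian = "big")
  for (i in seq_len(nrow(images))) {
    q <- as.integer(round(pmin(1, pmax(0, images[i, ])) * 255))
    writeBin(as.raw(as.vector(t(matrix(q, side, side)))), con)
  }
  invisible(path)
}
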