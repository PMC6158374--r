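#' Default sampling ranges for synthetic digit glyphs
#'
#' The synthetic stimulus generator renders parametric "6"-like and "9"-like
#' glyphs (a closed loop plus a curved tail; a handwritten "9" is rendered as
#' the half-turn rotation of a "6").  These ranges emulate the variability of
#' handwritten digits: orientation jitter, overall scale, stroke width, loop
#' radius and in-frame translation.  They are chosen once as a realistic
#' stated world and are not tuning knobs; widening them can push glyphs out of
#' the 28x28 frame, which [generate_digits()] rejects.
#'
#' @param orientation length-2 range of rotation angles, radians.
#' @param scale length-2 range of relative glyph size (1 = nominal).
#' @param stroke_width length-2 range of stroke widths, pixels.
#' @param circle_radius length-2 range of loop radii, in normalized glyph
#'   units (nominal 0.45).
#' @param translation length-2 range of horizontal/vertical offsets, pixels.
#' @return A named list of ranges with class `"glyph_param_ranges"`.
#' @export
#' @examples
#' r <- glyph_param_ranges()
#' r$orientation
glyph_param_ranges <- function(orientation = c(-0.45, 0.45),
                               scale = c(0.80, 1.05),
                               stroke_width = c(1.4, 2.4),
                               circle_radius = c(0.38, 0.52),
                               translation = c(-1.5, 1.5)) {
  rng <- list(orientation = orientation, scale = scale,
              stroke_width = stroke_width, circle_radius = circle_radius,
              translation = translation)
  for (nm in names(rng)) {
    v <- rng[[nm]]
    if (!is.numeric(v) || length(v) != 2L || v[1] > v[2])
      stop("glyph parameter range '", nm, "' must be a non-decreasing length-2 numeric")
  }
  structure(rng, class = "glyph_param_ranges")
}

# Base path of a "6" in normalized coordinates ([-1, 1] frame):
# a closed loop in the lower half plus a tail sweeping up to the right.
# A "9" is this path rotated by pi.
.glyph_path <- function(class, orientation, circle_radius, n_pts = 160L) {
  r <- circle_radius
  cy <- -(1 - r) * 0.62           # loop center sits low in the frame
  th <- seq(0, 2 * pi, length.out = n_pts)
  loop <- cbind(r * cos(th), cy + r * sin(th))
  # tail: quadratic Bezier from the loop's upper-right to the top right corner
  p0 <- c(r * cos(pi / 3), cy + r * sin(pi / 3))
  p1 <- c(r * 1.25, cy + r * 1.9)
  p2 <- c(r * 0.95, 0.78)
  tt <- seq(0, 1, length.out = n_pts %/% 2L)
  tail <- cbind((1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1],
                (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2])
  pts <- rbind(loop, tail)
  ang <- orientation + if (class == 9) pi else 0
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L, 2L)
  pts %*% t(rot)
}

# Render one glyph to a 28x28 matrix of intensities in [0, 1].
# Anti-aliased stroke: intensity decays linearly over one pixel beyond the
# stroke half-width, measured as distance to the sampled path.
render_glyph <- function(params, side = 28L) {
  stopifnot(is.list(params))
  pts <- .glyph_path(params$class, params$orientation, params$circle_radius)
  half_extent <- (side - 1) / 2
  px <- half_extent + 1 + params$scale * half_extent * 0.82 * pts[, 1] + params$dx
  py <- half_extent + 1 - params$scale * half_extent * 0.82 * pts[, 2] - params$dy
  margin <- params$stroke_width / 2 + 0.5
  if (any(px < 1 + margin - 0.5) || any(px > side - margin + 0.5) ||
      any(py < 1 + margin - 0.5) || any(py > side - margin + 0.5))
    stop("glyph parameters place the stroke outside the ", side, "x", side,
         " frame; tighten param_ranges (scale/translation/circle_radius)",
         call. = FALSE)
  gx <- matrix(rep(seq_len(side), each = side), nrow = side)   # column coord
  gy <- matrix(rep(seq_len(side), times = side), nrow = side)  # row coord
  d2 <- matrix(Inf, side, side)
  for (i in seq_len(nrow(pts))) {
    d2 <- pmin(d2, (gx - px[i])^2 + (gy - py[i])^2)
  }
  d <- sqrt(d2)
  img <- pmin(1, pmax(0, 1 - (d - params$stroke_width / 2)))
  img
}

.sample_glyph_params <- function(class, ranges) {
  ru <- function(r) stats::runif(1L, r[1], r[2])
  list(class = class,
       orientation = ru(ranges$orientation),
       scale = ru(ranges$scale),
       stroke_width = ru(ranges$stroke_width),
       circle_radius = ru(ranges$circle_radius),
       dx = ru(ranges$translation),
       dy = ru(ranges$translation))
}

#' Generate synthetic digit-like stimulus images
#'
#' Renders `n` grayscale 28x28 glyphs imitating handwritten digits "6" and
#' "9" (the "9" is the half-turn rotation of the "6" path, as in handwriting),
#' with orientation, scale, stroke width, loop radius and translation sampled
#' from `param_ranges`.  Deterministic for a fixed `seed`.
#'
#' @param n number of images (>= 1).
#' @param class_mix proportion of class "6"; exactly `round(n * class_mix)`
#'   images are of class 6 (balanced counts by construction, then shuffled).
#' @param param_ranges a [glyph_param_ranges()] object.
#' @param seed integer RNG seed (required; the generator is a stated world).
#' @param side image side length in pixels.
#' @return An object of class `"stimulus_set"`: a list with `images` (an
#'   `n x side^2` matrix, pixels in `[0, 1]`, column-major within each image),
#'   `labels` (integer vector of 6/9), `params` (data frame of the true glyph
#'   parameters) and `side`.
#' @export
#' @examples
#' s <- generate_digits(4, seed = 1)
#' table(s$labels)
generate_digits <- function(n, class_mix = 0.5,
                            param_ranges = glyph_param_ranges(),
                            seed, side = 28L) {
  stopifnot(n >= 1, class_mix >= 0, class_mix <= 1)
  if (missing(seed)) stop("generate_digits() requires an explicit seed")
  if (!inherits(param_ranges, "glyph_param_ranges"))
    param_ranges <- do.call(glyph_param_ranges, param_ranges)
  local_seed(seed, {
    n6 <- round(n * class_mix)
    labels <- c(rep(6L, n6), rep(9L, n - n6))
    labels <- labels[sample.int(n)]
    images <- matrix(0, n, side * side)
    plist <- vector("list", n)
    for (i in seq_len(n)) {
      p <- .sample_glyph_params(labels[i], param_ranges)
      images[i, ] <- as.vector(render_glyph(p, side))
      plist[[i]] <- p
    }
    params <- do.call(rbind, lapply(plist, function(p)
      data.frame(class = p$class, orientation = p$orientation, scale = p$scale,
                 stroke_width = p$stroke_width, circle_radius = p$circle_radius,
                 dx = p$dx, dy = p$dy)))
    structure(list(images = images, labels = labels, params = params,
                   side = side, seed = seed),
              class = "stimulus_set")
  })
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d images (%dx%d), classes: %s\n",
              nrow(x$images), x$side, x$side,
              paste(sprintf("%d x '%s'", table(x$labels), names(table(x$labels))),
                    collapse = ", ")))
  invisible(x)
}

#' Convert one stored image row back to a matrix
#'
#' @param images an image matrix (rows = stimuli) or a `stimulus_set`.
#' @param i row index.
#' @return A `side x side` numeric matrix.
#' @export
image_matrix <- function(images, i = 1L) {
  if (inherits(images, "stimulus_set")) images <- images$images
  side <- as.integer(sqrt(ncol(images)))
  matrix(images[i, ], side, side)
}
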