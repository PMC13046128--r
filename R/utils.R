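# Internal helpers shared across modules.
#
# Image convention: a 2-D image is a numeric matrix `img[y, x]` with y = row
# index increasing downward (as read from TIFF) and x = column index
# increasing rightward. Point coordinates are always (x, y) in pixel units;
# the centre of pixel img[r, c] is (x = c, y = r).

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' @noRd
wrap360 <- function(theta) {
  out <- theta %% 360
  # guard against -1e-14 %% 360 == 360 after floating rounding
  out[out >= 360] <- 0
  out
}

# Signed circular difference a - b mapped to (-180, 180].
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# Unsigned arc distance in degrees, in [0, 180].
arc_dist_deg <- function(a, b) abs(circ_diff_deg(a, b))

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

# Bilinear interpolation of matrix `img[y, x]` at (x, y); clamps to the border.
bilinear_at <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- min(max(x, 1), w)
  y <- min(max(y, 1), h)
  x0 <- floor(x); x1 <- min(x0 + 1, w)
  y0 <- floor(y); y1 <- min(y0 + 1, h)
  fx <- x - x0; fy <- y - y0
  img[y0, x0] * (1 - fx) * (1 - fy) + img[y0, x1] * fx * (1 - fy) +
    img[y1, x0] * (1 - fx) * fy + img[y1, x1] * fx * fy
}

# Deterministic stream of child seeds below 2^31, for per-section randomness.
derive_seeds <- function(seed, n) {
  stopifnot_scalar_number(seed, "seed")
  (as.double(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}
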