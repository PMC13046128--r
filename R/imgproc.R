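# Channel image processing: z-projection, gray-matter masking, rolling-ball
# background subtraction, maximum-entropy thresholding and binary cleanup.
#
# The canonical order is max_project -> apply_mask -> subtract_background ->
# threshold_max_entropy -> binarize_clean; `segment_channel()` runs the
# whole chain.

#' Channel z-stack container
#'
#' A single marker's z-stack with pixel calibration. Voxels are stored as a
#' 3-D array `[y, x, z]` in the unsigned 16-bit range.
#'
#' @param voxels numeric 3-D array `[y, x, z]` (a 2-D matrix is treated as a
#'   single plane).
#' @param pixel_size pixel calibration in micrometres per pixel.
#' @param marker marker label (e.g. `"ChAT"`).
#' @return object of class `"channel_stack"`.
#' @export
channel_stack <- function(voxels, pixel_size, marker = "unknown") {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L || dim(voxels)[3] < 1L) {
    stop("voxels must be a [y, x, z] array with at least one plane",
         call. = FALSE)
  }
  stopifnot_scalar_number(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  structure(list(voxels = voxels, pixel_size = pixel_size, marker = marker),
            class = "channel_stack")
}

#' Maximum-intensity projection of a z-stack
#'
#' Collapses a z-stack to 2-D by taking the per-pixel maximum across planes.
#'
#' @param stack a [channel_stack()] or a 3-D array `[y, x, z]`.
#' @return numeric matrix of the same spatial shape.
#' @export
max_project <- function(stack) {
  v <- if (inherits(stack, "channel_stack")) stack$voxels else stack
  if (is.matrix(v)) return(v)
  if (!is.array(v) || length(dim(v)) != 3L || dim(v)[3] < 1L) {
    stop("empty or malformed stack", call. = FALSE)
  }
  out <- v[, , 1]
  for (z in seq_len(dim(v)[3])[-1]) out <- pmax(out, v[, , z])
  out
}

#' Zero all pixels outside the gray-matter mask
#'
#' @param image numeric matrix.
#' @param gray_mask binary matrix of the same shape (non-zero = inside).
#' @return masked image.
#' @export
apply_mask <- function(image, gray_mask) {
  if (!identical(dim(image), dim(gray_mask))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  image * (gray_mask != 0)
}

#' Rolling-ball background subtraction
#'
#' Estimates the smoothly varying background by grayscale morphological
#' opening with a flat disk structuring element of the given radius (the
#' flat-ball approximation of the classical rolling-ball estimator) and
#' subtracts it, clamping at zero. Features narrower than the ball survive
#' with most of their amplitude; structures wider than the ball are treated
#' as background.
#'
#' @param image numeric matrix.
#' @param radius_px ball radius in pixels (default 20).
#' @param mask optional binary matrix marking valid (tissue) pixels. A
#'   masked image is zero outside the tissue, which would drag the opening
#'   down near the tissue edge and leave a bright rim after subtraction;
#'   with a mask, out-of-mask pixels are treated as no-data (filled with
#'   the in-mask maximum before the opening) and zeroed again afterwards.
#' @return background-subtracted image, everywhere `<=` the input inside
#'   the mask and `>= 0`.
#' @export
subtract_background <- function(image, radius_px = 20, mask = NULL) {
  stopifnot_scalar_number(radius_px, "radius_px")
  if (radius_px < 1) stop("radius must be >= 1 pixel", call. = FALSE)
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  work <- image
  if (!is.null(mask)) {
    if (!identical(dim(image), dim(mask))) {
      stop("image and mask shapes differ", call. = FALSE)
    }
    inside <- mask != 0
    if (!any(inside)) stop("mask selects no pixels", call. = FALSE)
    work[!inside] <- max(image[inside])
  }
  # EBImage grayscale morphology saturates outside [0, 1]; rescale around it
  scale <- max(work, 1)
  bg <- EBImage::opening(work / scale, brush) * scale
  out <- image - bg
  out[out < 0] <- 0
  if (!is.null(mask)) out[mask == 0] <- 0
  out
}

#' Maximum-entropy threshold of in-mask intensities
#'
#' Kapur-Sahoo-Wong threshold: builds a 256-bin histogram of the pixels
#' inside the gray-matter mask (bins spanning the observed in-mask
#' min..max, so 16-bit input reproduces the 8-bit-histogram dialect of the
#' common implementation) and returns the cut maximising the summed Shannon
#' entropies of the background and foreground partitions. Empty partitions
#' contribute zero entropy; ties are broken toward the lower threshold.
#' Out-of-mask pixels never enter the histogram — masking floods the zero
#' bin and would otherwise corrupt the optimum.
#'
#' @param image numeric matrix.
#' @param gray_mask binary matrix of the same shape; `NULL` uses all pixels.
#' @param n_bins histogram resolution (default 256).
#' @return threshold as an intensity value; foreground is `image >`
#'   threshold.
#' @export
threshold_max_entropy <- function(image, gray_mask = NULL, n_bins = 256L) {
  vals <- if (is.null(gray_mask)) as.vector(image) else {
    if (!identical(dim(image), dim(gray_mask))) {
      stop("image and mask shapes differ", call. = FALSE)
    }
    image[gray_mask != 0]
  }
  if (length(vals) == 0L) stop("mask selects no pixels", call. = FALSE)
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) {
    stop("degenerate histogram: constant in-mask image", call. = FALSE)
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(vals, breaks, rightmost.closed = TRUE), 1L),
         n_bins),
    nbins = n_bins)
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  cp <- cumsum(p)          # P(bin <= t)
  cs <- cumsum(plogp)      # sum of p log p up to t
  total_s <- cs[n_bins]
  # candidate t = last background bin, t in 1..n_bins-1
  t_idx <- seq_len(n_bins - 1L)
  Pb <- cp[t_idx]; Pf <- 1 - Pb
  Hb <- ifelse(Pb > 0, log(Pb) - cs[t_idx] / Pb, 0)
  Hf <- ifelse(Pf > 0, log(Pf) - (total_s - cs[t_idx]) / Pf, 0)
  obj <- Hb + Hf
  best <- which(obj >= max(obj) - 1e-12)[1]  # tie -> lower threshold
  breaks[best + 1L]
}

#' Binarise and clean a thresholded image
#'
#' Converts to binary with `image > threshold`, removes speckle with a
#' single 3x3 median (majority) pass, then applies one iteration of
#' morphological closing with a 3x3 square structuring element.
#'
#' @param image numeric matrix.
#' @param threshold intensity cut; foreground is strictly above it.
#' @return binary (0/1) matrix.
#' @export
binarize_clean <- function(image, threshold) {
  stopifnot_scalar_number(threshold, "threshold")
  bin <- (image > threshold) * 1
  # 3x3 binary median = majority of the 9-neighbourhood (border replicated)
  bin <- (box_sum3(bin) >= 5) * 1
  bin <- EBImage::closing(bin, matrix(1L, 3L, 3L))
  (bin != 0) * 1
}

# Sum over the replicated-border 3x3 neighbourhood of every pixel, via
# cumulative sums (much faster than convolution for large images).
box_sum3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[h + 2L, ] <- pad[h + 1L, ]
  pad[, 1] <- pad[, 2]; pad[, w + 2L] <- pad[, w + 1L]
  cs <- apply(pad, 2, cumsum)
  rowband <- cs[3:(h + 2), ] - rbind(0, cs)[1:h, ]
  cs2 <- t(apply(rowband, 1, cumsum))
  cs2[, 3:(w + 2)] - cbind(0, cs2)[, 1:w]
}

#' Segment one channel into a candidate-cell mask
#'
#' The full per-channel chain: maximum projection, gray-matter masking,
#' rolling-ball background subtraction, maximum-entropy thresholding
#' (computed on in-mask pixels only, with an optional manual override) and
#' binary cleanup. The cleaned mask is re-masked so cleanup cannot leak
#' outside the tissue.
#'
#' @inheritParams max_project
#' @param geometry a [section_geometry()] supplying the gray-matter mask.
#' @param ball_radius_px rolling-ball radius in pixels.
#' @param manual_threshold optional intensity overriding the automatic
#'   maximum-entropy value.
#' @return list with `mask` (binary matrix), `threshold`, and the
#'   background-subtracted projection `image`.
#' @export
segment_channel <- function(stack, geometry, ball_radius_px = 20,
                            manual_threshold = NULL) {
  proj <- max_project(stack)
  proj <- apply_mask(proj, geometry$gray_mask)
  proj <- subtract_background(proj, ball_radius_px, mask = geometry$gray_mask)
  thr <- if (is.null(manual_threshold)) {
    threshold_max_entropy(proj, geometry$gray_mask)
  } else manual_threshold
  mask <- binarize_clean(proj, thr)
  mask <- apply_mask(mask, geometry$gray_mask)
  list(mask = mask, threshold = thr, image = proj)
}
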