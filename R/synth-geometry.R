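# Synthetic section geometry: butterfly-shaped gray matter and central
# canal, bilaterally symmetric by construction.

# Evaluate a rotated-ellipse inside test on micrometre coordinates.
# `x_um`/`y_um` are vectors relative to the canal; mirrored lobes use |x|.
inside_ellipse <- function(x_um, y_um, ell, mirror = FALSE) {
  if (mirror) x_um <- abs(x_um)
  xr <- x_um - ell$center[1]
  yr <- y_um - ell$center[2]
  th <- deg2rad(ell$rot_deg %||% 0)
  xa <- xr * cos(th) + yr * sin(th)
  ya <- -xr * sin(th) + yr * cos(th)
  (xa / ell$semi[1])^2 + (ya / ell$semi[2])^2 <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the spatial reference frame of a synthetic section
#'
#' Rasterises the butterfly gray matter (central band plus mirrored
#' ventral- and dorsal-horn ellipse lobes) and a disk-shaped central canal
#' centred on the vertical midline. The gray-matter mask is bilaterally
#' symmetric about the midline by construction, and the canal must fit
#' strictly inside the gray matter.
#'
#' @param config a [section_config()].
#' @return a [section_geometry()] with `dorsal_up = TRUE`.
#' @export
make_section_geometry <- function(config) {
  if (!inherits(config, "section_config")) {
    stop("config must be a section_config", call. = FALSE)
  }
  h <- config$image_size[1]; w <- config$image_size[2]
  ps <- config$pixel_size
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- (seq_len(w) - cx) * ps
  ys <- (cy - seq_len(h)) * ps  # dorsal (up) positive
  xg <- matrix(xs, h, w, byrow = TRUE)
  yg <- matrix(ys, h, w)
  gm <- config$gray_matter
  gray <- inside_ellipse(xg, yg, gm$band) |
    inside_ellipse(xg, yg, gm$ventral, mirror = TRUE) |
    inside_ellipse(xg, yg, gm$dorsal, mirror = TRUE)
  gray <- gray * 1
  canal <- ((xg^2 + yg^2) <= config$canal_radius_um^2) * 1
  if (sum(canal) == 0) {
    stop("canal radius smaller than one pixel", call. = FALSE)
  }
  if (any(canal == 1 & gray == 0)) {
    stop("configuration error: canal not contained in the gray matter",
         call. = FALSE)
  }
  if (sum(gray) <= sum(canal)) {
    stop("configuration error: gray matter no larger than the canal",
         call. = FALSE)
  }
  section_geometry(gray, canal, canal_centroid = c(x = cx, y = cy),
                   dorsal_up = TRUE, pixel_size = ps)
}
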