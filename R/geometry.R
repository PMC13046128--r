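# Canal-referenced polar coordinates, laterality mirroring and gray-matter
# distance normalisation.

#' Section spatial reference frame
#'
#' Gray-matter mask, central-canal mask and centroid, and the orientation
#' flag saying whether the dorsal side is at the top of the image (small
#' row indices).
#'
#' @param gray_mask,canal_mask binary matrices of equal shape.
#' @param canal_centroid optional `(x, y)` in pixels; computed from
#'   `canal_mask` when omitted.
#' @param dorsal_up `TRUE` when dorsal is at the top of the image.
#' @param pixel_size micrometres per pixel.
#' @return object of class `"section_geometry"`.
#' @export
section_geometry <- function(gray_mask, canal_mask, canal_centroid = NULL,
                             dorsal_up = TRUE, pixel_size = 1) {
  if (!identical(dim(gray_mask), dim(canal_mask))) {
    stop("gray and canal masks must share a shape", call. = FALSE)
  }
  if (is.null(canal_centroid)) canal_centroid <- roi_centroid(canal_mask)
  structure(list(gray_mask = (gray_mask != 0) * 1,
                 canal_mask = (canal_mask != 0) * 1,
                 canal_centroid = canal_centroid,
                 dorsal_up = isTRUE(dorsal_up),
                 pixel_size = pixel_size),
            class = "section_geometry")
}

#' Centroid of a binary region of interest
#'
#' Arithmetic mean of the member pixel coordinates.
#'
#' @param mask binary matrix; must contain at least one foreground pixel.
#' @return `c(x, y)` in pixels.
#' @export
roi_centroid <- function(mask) {
  idx <- which(mask != 0)
  if (length(idx) == 0L) stop("empty mask", call. = FALSE)
  h <- nrow(mask)
  c(x = mean(((idx - 1L) %/% h) + 1L), y = mean(((idx - 1L) %% h) + 1L))
}

#' Polar coordinates of a cell about the central canal
#'
#' Straight-line distance (scaled to micrometres) and orientation angle of
#' a cell centroid about the canal centroid, in the mathematical convention
#' where 0 deg points right and 90 deg points dorsal. Image rows increase
#' downward, so with `dorsal_up` the vertical offset sign is flipped before
#' the inverse tangent: a cell directly above the canal maps to 90 deg.
#'
#' @param cell_centroid,canal_centroid `(x, y)` positions in pixels.
#' @param pixel_size micrometres per pixel.
#' @param dorsal_up orientation flag (see [section_geometry()]).
#' @return list with `distance_um` and `angle_deg` in `[0, 360)`.
#' @export
polar_coords <- function(cell_centroid, canal_centroid, pixel_size = 1,
                         dorsal_up = TRUE) {
  stopifnot_scalar_number(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  dx <- cell_centroid[[1]] - canal_centroid[[1]]
  dy <- cell_centroid[[2]] - canal_centroid[[2]]
  if (dx == 0 && dy == 0) {
    stop("cell coincides with the canal centroid: angle undefined",
         call. = FALSE)
  }
  vert <- if (dorsal_up) -dy else dy
  list(distance_um = sqrt(dx^2 + dy^2) * pixel_size,
       angle_deg = wrap360(rad2deg(atan2(vert, dx))))
}

#' Laterality correction by mirroring left-side angles
#'
#' Free-floating sections have no identifiable anatomical left/right, so
#' angles strictly between 90 and 270 deg (the left side) are reflected
#' onto the right with `theta' = 180 - theta`, wrapped to `[0, 360)`.
#' Angles at exactly 90 or 270 deg and all right-side angles are unchanged.
#' The dorsoventral component is preserved (`sin` is invariant) and the
#' transform is idempotent.
#'
#' @param theta numeric vector of angles in degrees.
#' @return mirrored angles in `[270, 360) U [0, 90]`.
#' @export
mirror_left_to_right <- function(theta) {
  theta <- wrap360(theta)
  left <- theta > 90 & theta < 270
  theta[left] <- wrap360(180 - theta[left])
  theta
}

#' Normalised radial distance within the gray matter
#'
#' Converts a cell's position into a unitless depth relative to the gray
#' matter, correcting for tissue-size differences between sections. Three
#' variants are provided:
#'
#' * `"radial_fraction"` (default): distance from the canal centroid
#'   divided by the distance from the canal centroid to the gray-matter
#'   boundary along the same ray; 0 at the canal, 1 at the boundary.
#' * `"edge_map"`: the Euclidean distance-transform value of the gray-matter
#'   mask (distance from the tissue edge), sampled at the cell by bilinear
#'   interpolation, divided by the transform's maximum.
#' * `"canal_over_depthmax"`: distance from the canal divided by the
#'   distance-transform maximum.
#'
#' The default follows the bounded 0-at-canal / 1-at-boundary semantics;
#' the other variants are literal and hybrid readings of an edge-distance
#' map and are retained for comparison.
#'
#' @param cell_centroid `(x, y)` in pixels; must lie inside the gray-matter
#'   mask.
#' @param geometry a [section_geometry()].
#' @param variant one of `"radial_fraction"`, `"edge_map"`,
#'   `"canal_over_depthmax"`.
#' @return unitless value `>= 0` (in `[0, 1]` for `"radial_fraction"`).
#' @export
normalise_distance <- function(cell_centroid, geometry,
                               variant = c("radial_fraction", "edge_map",
                                           "canal_over_depthmax")) {
  variant <- match.arg(variant)
  mask <- geometry$gray_mask
  h <- nrow(mask); w <- ncol(mask)
  cx <- cell_centroid[[1]]; cy <- cell_centroid[[2]]
  if (round(cy) < 1 || round(cy) > h || round(cx) < 1 || round(cx) > w ||
      mask[round(cy), round(cx)] == 0) {
    stop("cell lies outside the gray-matter mask", call. = FALSE)
  }
  canal <- geometry$canal_centroid
  if (variant == "radial_fraction") {
    dx <- cx - canal[[1]]; dy <- cy - canal[[2]]
    r_cell <- sqrt(dx^2 + dy^2)
    if (r_cell == 0) return(0)
    ux <- dx / r_cell; uy <- dy / r_cell
    step <- 0.25
    radii <- seq(r_cell + step, sqrt(h^2 + w^2) + step, by = step)
    rx <- round(canal[[1]] + ux * radii)
    ry <- round(canal[[2]] + uy * radii)
    outside <- rx < 1 | rx > w | ry < 1 | ry > h
    outside[!outside] <- mask[cbind(ry[!outside], rx[!outside])] == 0
    first_out <- which(outside)[1]
    if (is.na(first_out)) {
      stop("degenerate ray: no boundary crossing", call. = FALSE)
    }
    r_boundary <- radii[first_out] - step / 2
    min(r_cell / r_boundary, 1)
  } else {
    D <- edge_distance_map(geometry)
    if (variant == "edge_map") {
      bilinear_at(D, cx, cy) / max(D)
    } else {
      dist_px <- sqrt((cx - canal[[1]])^2 + (cy - canal[[2]])^2)
      dist_px / max(D)
    }
  }
}

# Euclidean distance transform of the gray-matter mask (distance of each
# in-mask pixel from the tissue edge), cached on the geometry's environment
# is avoided for simplicity; callers batch via `edge_distance_map()`.
edge_distance_map <- function(geometry) {
  if (!is.null(geometry$edge_map)) return(geometry$edge_map)
  EBImage::distmap(geometry$gray_mask)
}

#' Precompute and attach the edge-distance map to a geometry
#'
#' Avoids recomputing the distance transform when normalising many cells of
#' one section with the `"edge_map"` or `"canal_over_depthmax"` variants.
#'
#' @param geometry a [section_geometry()].
#' @return the geometry with an `edge_map` field attached.
#' @export
with_edge_map <- function(geometry) {
  geometry$edge_map <- EBImage::distmap(geometry$gray_mask)
  geometry
}
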