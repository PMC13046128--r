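# Size-filtered particle extraction per marker, ChAT size subclassing and
# double-positive detection by ROI overlap fraction.

#' Area of a circular soma from its diameter
#'
#' `pi * (d / 2)^2`, the conversion behind all marker size windows.
#'
#' @param d_um diameter(s) in micrometres, `>= 0`.
#' @return area(s) in square micrometres.
#' @examples
#' round(diameter_to_area(c(10, 40)), 1) # 78.5, 1256.6
#' @export
diameter_to_area <- function(d_um) {
  if (!is.numeric(d_um) || any(!is.finite(d_um)) || any(d_um < 0)) {
    stop("diameters must be finite and non-negative", call. = FALSE)
  }
  pi * (d_um / 2)^2
}

#' Marker-specific particle size window
#'
#' Inclusive area window `[a_min, a_max]` in square micrometres derived from
#' a diameter range. The stock windows used for the four markers are
#' available from [marker_size_windows()].
#'
#' @param marker marker label.
#' @param d_min,d_max diameter bounds in micrometres, `0 < d_min < d_max`.
#' @return object of class `"size_window"` with fields `marker`, `d_min`,
#'   `d_max`, `a_min`, `a_max`.
#' @export
size_window <- function(marker, d_min, d_max) {
  stopifnot_scalar_number(d_min, "d_min")
  stopifnot_scalar_number(d_max, "d_max")
  if (d_min <= 0 || d_max <= d_min) stop("need 0 < d_min < d_max",
                                         call. = FALSE)
  structure(list(marker = marker, d_min = d_min, d_max = d_max,
                 a_min = diameter_to_area(d_min),
                 a_max = diameter_to_area(d_max)),
            class = "size_window")
}

#' Stock size windows for the four markers
#'
#' ChAT 10-40 um diameter, Parvalbumin 10-20 um, GAD-67 8-20 um,
#' Calbindin 10-25 um.
#'
#' @return named list of [size_window()] objects.
#' @export
marker_size_windows <- function() {
  list(ChAT        = size_window("ChAT", 10, 40),
       GAD67       = size_window("GAD67", 8, 20),
       Parvalbumin = size_window("Parvalbumin", 10, 20),
       Calbindin   = size_window("Calbindin", 10, 25))
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a union-find pass over the four
# diagonal offsets.
label_components8 <- function(binary) {
  lab <- EBImage::bwlabel(binary != 0)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nmax <- max(lab)
  if (nmax < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- list(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))  # down-left
  e <- do.call(rbind, pairs)
  e <- e[e[, 1] > 0 & e[, 2] > 0 & e[, 1] != e[, 2], , drop = FALSE]
  parent <- seq_len(nmax)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      a <- find(e[r, 1]); b <- find(e[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Extract size-filtered particles from a binary mask
#'
#' Finds 8-connected components, converts pixel counts to areas with the
#' pixel calibration, and keeps components whose area falls inside the
#' window (inclusive at both bounds). Centroids are arithmetic means of
#' member pixel coordinates. Touching cells are not split.
#'
#' @param binary binary matrix from [binarize_clean()].
#' @param pixel_size micrometres per pixel.
#' @param window a [size_window()], or `NULL` to keep every component.
#' @return data frame with one row per retained cell: `id`, `marker`,
#'   `x`, `y` (centroid, pixels), `n_px`, `area_um2`; the pixel sets are
#'   attached as the `"pixels"` attribute (list of linear index vectors).
#' @export
find_particles <- function(binary, pixel_size, window = NULL) {
  stopifnot_scalar_number(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  lab <- label_components8(binary)
  marker <- if (is.null(window)) NA_character_ else window$marker
  if (max(lab) == 0L) {
    out <- data.frame(id = integer(0), marker = character(0),
                      x = numeric(0), y = numeric(0),
                      n_px = integer(0), area_um2 = numeric(0))
    attr(out, "pixels") <- list()
    return(out)
  }
  idx <- which(lab > 0)
  comp <- lab[idx]
  n_px <- tabulate(comp)
  h <- nrow(binary)
  ys <- ((idx - 1L) %% h) + 1L
  xs <- ((idx - 1L) %/% h) + 1L
  cx <- as.vector(tapply(xs, comp, mean))
  cy <- as.vector(tapply(ys, comp, mean))
  area <- n_px * pixel_size^2
  keep <- if (is.null(window)) rep(TRUE, length(n_px)) else {
    area >= window$a_min & area <= window$a_max
  }
  ids <- which(keep)
  pixels <- split(idx, comp)[as.character(ids)]
  out <- data.frame(id = seq_along(ids), marker = marker,
                    x = cx[ids], y = cy[ids],
                    n_px = n_px[ids], area_um2 = area[ids])
  attr(out, "pixels") <- unname(pixels)
  out
}

#' Split ChAT-positive cells into size classes
#'
#' Cells of 10-25 um diameter (area in `[78.5, 491)` um^2) are labelled
#' interneurons; 25-40 um (area in `[491, 1257]` um^2) motor neurons. The
#' 491 um^2 boundary is assigned to the motor-neuron class. Areas outside
#' the ChAT window are an upstream filtering failure and raise an error.
#'
#' @param area_um2 numeric vector of ChAT cell areas in square micrometres.
#' @return character vector, `"interneuron"` or `"motor_neuron"`.
#' @export
classify_chat_size <- function(area_um2) {
  w <- marker_size_windows()$ChAT
  if (any(area_um2 < w$a_min - 1e-9 | area_um2 > w$a_max + 1e-9)) {
    stop("area outside the ChAT size window; filter upstream", call. = FALSE)
  }
  split_at <- diameter_to_area(25)
  ifelse(area_um2 < split_at, "interneuron", "motor_neuron")
}

#' Fraction of a cell's pixels overlapping another marker's mask
#'
#' `|pixels(cell) intersect foreground(B)| / |pixels(cell)|`. The cell ROI
#' is always defined on the first-listed (anchor) marker; overlap of A in B
#' and B in A generally differ.
#'
#' @param pixels linear pixel indices of the cell (as stored by
#'   [find_particles()]).
#' @param other_binary binary matrix of marker B, same image shape.
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(pixels, other_binary) {
  if (length(pixels) == 0L) stop("empty pixel set", call. = FALSE)
  sum(other_binary[pixels] != 0) / length(pixels)
}

#' Double-positive cells by overlap cutoff
#'
#' Retains the anchor-marker cells whose overlap fraction with marker B's
#' binary mask is at least `cutoff` (default 20%, chosen to exclude edge
#' touches while keeping genuine co-expression). The fraction is stored in
#' a `coexpr_<marker>` column for every cell.
#'
#' @param cells data frame from [find_particles()] (with its `"pixels"`
#'   attribute).
#' @param binary_b binary mask of the second marker.
#' @param cutoff minimum overlap fraction in `[0, 1]`.
#' @param marker_b label used for the stored fraction column.
#' @return `cells` with the fraction column added and only rows meeting the
#'   cutoff; the `"pixels"` attribute is subset accordingly.
#' @export
double_positives <- function(cells, binary_b, cutoff = 0.20,
                             marker_b = "B") {
  stopifnot_scalar_number(cutoff, "cutoff")
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]",
                                     call. = FALSE)
  px <- attr(cells, "pixels")
  frac <- vapply(px, overlap_fraction, numeric(1),
                 other_binary = binary_b)
  if (nrow(cells) == 0L) frac <- numeric(0)
  cells[[paste0("coexpr_", marker_b)]] <- frac
  keep <- frac >= cutoff
  out <- cells[keep, , drop = FALSE]
  attr(out, "pixels") <- px[keep]
  out
}
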