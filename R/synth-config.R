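# Configuration objects for the synthetic-section generator.
#
# All physical quantities are in micrometres; the canal sits at the image
# centre with x increasing rightward and dorsal "up" (toward small row
# indices).

#' Specification of one synthetic cell population
#'
#' A population is a set of cells sharing a marker set, a diameter range,
#' an angular law (von Mises mixture or uniform, in the 0-right / 90-dorsal
#' convention) and a radial law over normalised depth between the canal and
#' the gray-matter boundary.
#'
#' @param name population label (free text, kept in the ground truth).
#' @param markers character vector of marker flags, subset of
#'   `c("ChAT", "GAD67", "Parvalbumin", "Calbindin")`.
#' @param count number of cells per section, `>= 0`.
#' @param diameter_um length-2 range of soma diameters, within `(0, 60]`.
#' @param angular either `list(kind = "uniform")` or
#'   `list(kind = "vonmises", mu_deg = ..., kappa = ..., weight = ...)`
#'   where the three vectors describe mixture components (`kappa >= 0`).
#' @param radial either `list(kind = "uniform")` or
#'   `list(kind = "beta", shape1 = ..., shape2 = ...)` over normalised
#'   depth in `[0, 1]` (0 = innermost placeable radius, 1 = outermost).
#' @return object of class `"population_spec"`.
#' @export
population_spec <- function(name, markers, count,
                            diameter_um,
                            angular = list(kind = "uniform"),
                            radial = list(kind = "uniform")) {
  known <- c("ChAT", "GAD67", "Parvalbumin", "Calbindin")
  if (!all(markers %in% known)) {
    stop("unknown marker; expected subset of ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (length(markers) < 1L) stop("need at least one marker", call. = FALSE)
  stopifnot_scalar_number(count, "count")
  if (count < 0 || count != round(count)) {
    stop("count must be a non-negative integer", call. = FALSE)
  }
  if (length(diameter_um) != 2L || any(diameter_um <= 0) ||
      any(diameter_um > 60) || diameter_um[1] > diameter_um[2]) {
    stop("diameter range must lie within (0, 60] um", call. = FALSE)
  }
  if (identical(angular$kind, "vonmises")) {
    if (any(angular$kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
    if (is.null(angular$weight)) {
      angular$weight <- rep(1, length(angular$mu_deg))
    }
    angular$weight <- angular$weight / sum(angular$weight)
  }
  structure(list(name = name, markers = markers, count = as.integer(count),
                 diameter_um = diameter_um, angular = angular,
                 radial = radial),
            class = "population_spec")
}

#' Default synthetic populations
#'
#' Emulates the qualitative layout of an immunostained lumbar cross-
#' section: ChAT motor neurons concentrated in the ventral horns, smaller
#' peri-canal ChAT interneurons, GAD-67 cells concentrated in the lateral
#' intermediate zone, peripheral Parvalbumin cells and dorsally biased
#' Calbindin cells. Mixture components come in mirrored pairs so the
#' section is statistically bilateral; after laterality mirroring the
#' motor-neuron mass sits at 315 deg, GAD-67 near 5 deg and Calbindin near
#' 60 deg, with concentrations comparable to real mirrored-angle samples.
#' Diameter ranges sit inside the marker detection windows (including those
#' of co-expressed partner markers) with a margin so rasterisation cannot
#' push a cell across a window bound.
#'
#' @return named list of [population_spec()] objects; ~165 placed cells
#'   carrying ~200 marker-positive labels per section.
#' @export
default_populations <- function() {
  list(
    chat_motor = population_spec(
      "chat_motor", "ChAT", 25, c(27, 36),
      angular = list(kind = "vonmises", mu_deg = c(315, 225), kappa = 3,
                     weight = c(0.5, 0.5)),
      radial = list(kind = "beta", shape1 = 4, shape2 = 1.6)),
    chat_inter = population_spec(
      "chat_inter", "ChAT", 12, c(12, 18.5),
      angular = list(kind = "uniform"),
      radial = list(kind = "beta", shape1 = 1.5, shape2 = 4.5)),
    calb = population_spec(
      "calb", "Calbindin", 32, c(11, 21),
      angular = list(kind = "vonmises", mu_deg = c(60, 120), kappa = 1,
                     weight = c(0.5, 0.5)),
      radial = list(kind = "beta", shape1 = 2, shape2 = 2)),
    parv = population_spec(
      "parv", "Parvalbumin", 38, c(11, 19),
      angular = list(kind = "vonmises", mu_deg = c(15, 165), kappa = 2,
                     weight = c(0.5, 0.5)),
      radial = list(kind = "beta", shape1 = 2, shape2 = 1.6)),
    gad = population_spec(
      "gad", "GAD67", 58, c(10, 18),
      angular = list(kind = "vonmises", mu_deg = c(5, 175), kappa = 2.4,
                     weight = c(0.5, 0.5)),
      radial = list(kind = "beta", shape1 = 1.5, shape2 = 1.5))
  )
}

#' Default co-expression fractions
#'
#' Each rule adds a second marker flag to `round(fraction * count)` cells
#' of one population (exact bookkeeping, so recovery tests have integer
#' ground truth): 40% of peri-canal ChAT interneurons co-express GAD-67
#' (CSF-contacting cells), 90% of Parvalbumin cells co-express GAD-67
#' (fast-spiking GABAergic interneurons), and 15% of Parvalbumin cells
#' co-express Calbindin (the Renshaw subset).
#'
#' @return list of rules `list(population, marker, fraction)`.
#' @export
default_coexpression <- function() {
  list(
    list(population = "chat_inter", marker = "GAD67", fraction = 0.40),
    list(population = "parv", marker = "GAD67", fraction = 0.90),
    list(population = "parv", marker = "Calbindin", fraction = 0.15)
  )
}

#' Default butterfly gray-matter shape
#'
#' Union of a central elliptical band around the canal, two mirrored
#' ventral-horn lobes and two mirrored dorsal-horn lobes. Centres and
#' semi-axes are in micrometres relative to the canal; lobes given for the
#' right side are mirrored automatically.
#'
#' @return list of ellipse descriptors.
#' @export
default_gray_matter <- function() {
  list(
    band = list(center = c(0, 0), semi = c(280, 130), rot_deg = 0),
    ventral = list(center = c(130, -130), semi = c(130, 170), rot_deg = -20),
    dorsal = list(center = c(95, 160), semi = c(85, 155), rot_deg = 15)
  )
}

#' Synthetic-section configuration
#'
#' Bundles the image geometry, gray-matter shape, canal size, cell
#' populations, co-expression rules, intensity model and seed for one
#' synthetic section. Defaults emulate a 2x-binned 20x confocal tile of a
#' mouse lumbar cross-section (1.14 um/px, 640 x 640 px, 3-plane z-stack,
#' 16-bit intensities).
#'
#' @param image_size `c(height, width)` in pixels.
#' @param n_slices number of z-planes.
#' @param pixel_size micrometres per pixel.
#' @param gray_matter shape list as in [default_gray_matter()].
#' @param canal_radius_um central-canal radius.
#' @param populations named list of [population_spec()]s.
#' @param coexpression list of co-expression rules
#'   (see [default_coexpression()]).
#' @param background constant background intensity.
#' @param gradient_amplitude peak amplitude of the smooth background ramp.
#' @param noise_sd Gaussian pixel-noise standard deviation, `>= 0`.
#' @param cell_amplitude added intensity of a cell disk summed over the
#'   z-weights (the maximum projection recovers at least
#'   `max(z_weights) * cell_amplitude`).
#' @param z_weights per-plane intensity split of each cell (default
#'   `c(0.25, 0.5, 0.25)`).
#' @param min_separation if `TRUE`, enforce resolvable placements: centre
#'   distance at least the sum of the two soma radii plus a 4-pixel gap
#'   (the binary cleanup bridges smaller gaps). The default allows
#'   touching/overlapping cells as in real tissue.
#' @param seed integer seed controlling placement and rendering noise.
#' @return object of class `"section_config"`.
#' @export
section_config <- function(image_size = c(640, 640),
                           n_slices = 3,
                           pixel_size = 1.14,
                           gray_matter = default_gray_matter(),
                           canal_radius_um = 15,
                           populations = default_populations(),
                           coexpression = default_coexpression(),
                           background = 1000,
                           gradient_amplitude = 200,
                           noise_sd = 0,
                           cell_amplitude = 12000,
                           z_weights = c(0.25, 0.5, 0.25),
                           min_separation = FALSE,
                           seed = 1L) {
  stopifnot_scalar_number(pixel_size, "pixel_size")
  stopifnot_scalar_number(canal_radius_um, "canal_radius_um")
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(image_size) != 2L || any(image_size < 32)) {
    stop("image_size must be c(height, width), each >= 32", call. = FALSE)
  }
  if (n_slices < 1L) stop("need at least one z-plane", call. = FALSE)
  if (length(z_weights) != n_slices) {
    z_weights <- rep(1 / n_slices, n_slices)
  }
  z_weights <- z_weights / sum(z_weights)
  for (p in populations) {
    if (!inherits(p, "population_spec")) {
      stop("populations must be population_spec objects", call. = FALSE)
    }
  }
  for (rule in coexpression) {
    if (is.null(populations[[rule$population]])) {
      stop("co-expression rule refers to unknown population '",
           rule$population, "'", call. = FALSE)
    }
    if (rule$fraction < 0 || rule$fraction > 1) {
      stop("co-expression fraction must be in [0, 1]", call. = FALSE)
    }
  }
  structure(list(image_size = as.integer(image_size),
                 n_slices = as.integer(n_slices),
                 pixel_size = pixel_size, gray_matter = gray_matter,
                 canal_radius_um = canal_radius_um,
                 populations = populations, coexpression = coexpression,
                 background = background,
                 gradient_amplitude = gradient_amplitude,
                 noise_sd = noise_sd, cell_amplitude = cell_amplitude,
                 z_weights = z_weights,
                 min_separation = isTRUE(min_separation),
                 seed = as.integer(seed)),
            class = "section_config")
}

#' Marker labels used throughout the package
#' @return character vector of the four marker names.
#' @export
marker_names <- function() c("ChAT", "GAD67", "Parvalbumin", "Calbindin")
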