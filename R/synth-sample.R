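# Ground-truth cell placement for synthetic sections.

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` degenerates to the circular
#' uniform distribution.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration parameter, `>= 0`.
#' @return angles in degrees on `[0, 360)`.
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.3 * (n - length(out))))
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(m)
    acc <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    if (any(acc)) {
      u3 <- stats::runif(sum(acc))
      out <- c(out, mu + sign(u3 - 0.5) * acos(f[acc]))
    }
  }
  wrap360(rad2deg(out[seq_len(n)]))
}

# Draw n angles from a population's angular law (degrees).
sample_angular <- function(law, n) {
  if (identical(law$kind, "uniform")) return(stats::runif(n, 0, 360))
  comp <- sample.int(length(law$mu_deg), n, replace = TRUE,
                     prob = law$weight)
  kappa <- if (length(law$kappa) == 1L) rep(law$kappa, length(law$mu_deg)) else law$kappa
  out <- numeric(n)
  for (k in seq_along(law$mu_deg)) {
    sel <- comp == k
    out[sel] <- rvonmises(sum(sel), law$mu_deg[k], kappa[k])
  }
  out
}

# Draw n normalised depths in [0, 1] from a radial law.
sample_radial <- function(law, n) {
  if (identical(law$kind, "uniform")) return(stats::runif(n))
  stats::rbeta(n, law$shape1, law$shape2)
}

# Distance-transform of the gray mask used to guarantee whole-disk
# placement (cached on the geometry by callers when batching).
placement_fit_map <- function(geometry) {
  if (!is.null(geometry$fit_map)) return(geometry$fit_map)
  EBImage::distmap(geometry$gray_mask)
}

#' Place one population of ground-truth cells
#'
#' Rejection sampling: each cell draws an angle from the population's
#' angular law, a normalised depth from its radial law and a diameter
#' uniform in its range, then is positioned on the ray from the canal
#' centroid at that angle. Valid radii along the ray keep the whole soma
#' disk inside the gray matter (edge clearance of one soma radius plus one
#' pixel) and clear of the canal; the normalised depth indexes into that
#' valid set, so depth 0 is the innermost placeable radius and 1 the
#' outermost. A cell failing to place within 100 attempts raises a
#' placement error.
#'
#' @param spec a [population_spec()].
#' @param geometry a [section_geometry()] (typically from
#'   [make_section_geometry()]).
#' @param seed integer seed; identical seeds give identical placements.
#' @param min_separation if `TRUE`, enforce centre separation of at least
#'   the sum of soma radii plus one pixel against all previously placed
#'   cells (including those in `existing`).
#' @param existing optional data frame of already-placed cells (for
#'   cross-population separation).
#' @param retry_budget attempts allowed per cell.
#' @return data frame with one row per cell: `population`, `x_px`, `y_px`,
#'   `diameter_um`, `true_angle_deg`, `true_distance_um` and one logical
#'   flag column per marker.
#' @export
sample_population <- function(spec, geometry, seed = NULL,
                              min_separation = FALSE, existing = NULL,
                              retry_budget = 100L) {
  if (!inherits(spec, "population_spec")) {
    stop("spec must be a population_spec", call. = FALSE)
  }
  with_seed(seed, sample_population_impl(spec, geometry, min_separation,
                                         existing, retry_budget))
}

sample_population_impl <- function(spec, geometry, min_separation,
                                   existing, retry_budget) {
  n <- spec$count
  empty <- data.frame(population = character(0), x_px = numeric(0),
                      y_px = numeric(0), diameter_um = numeric(0),
                      true_angle_deg = numeric(0),
                      true_distance_um = numeric(0))
  for (m in marker_names()) empty[[m]] <- logical(0)
  if (n == 0L) return(empty)

  ps <- geometry$pixel_size
  fit <- placement_fit_map(geometry)
  canal <- geometry$canal_centroid
  h <- nrow(geometry$gray_mask); w <- ncol(geometry$gray_mask)
  canal_r_px <- sqrt(sum(geometry$canal_mask) / pi)

  prev_x <- numeric(0); prev_y <- numeric(0); prev_r <- numeric(0)
  if (min_separation && !is.null(existing) && nrow(existing)) {
    prev_x <- existing$x_px; prev_y <- existing$y_px
    prev_r <- existing$diameter_um / 2 / ps
  }

  out_x <- numeric(n); out_y <- numeric(n); out_d <- numeric(n)
  out_a <- numeric(n); out_r <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(retry_budget)) {
      theta <- sample_angular(spec$angular, 1)
      depth <- sample_radial(spec$radial, 1)
      d_um <- stats::runif(1, spec$diameter_um[1], spec$diameter_um[2])
      r_cell_px <- d_um / 2 / ps
      # direction in image coordinates (dorsal_up: angle 90 -> -y rows)
      ux <- cos(deg2rad(theta))
      uy <- if (geometry$dorsal_up) -sin(deg2rad(theta)) else sin(deg2rad(theta))
      r_min <- canal_r_px + r_cell_px + 1
      r_max <- sqrt(h^2 + w^2)
      radii <- seq(r_min, r_max, by = 1)
      px <- round(canal[[1]] + ux * radii)
      py <- round(canal[[2]] + uy * radii)
      inb <- px >= 1 & px <= w & py >= 1 & py <= h
      ok <- logical(length(radii))
      ok[inb] <- fit[cbind(py[inb], px[inb])] >= r_cell_px + 1
      valid <- radii[ok]
      if (length(valid) == 0L) next
      r_pick <- valid[pmax(1L, ceiling(depth * length(valid)))]
      x <- canal[[1]] + ux * r_pick
      y <- canal[[2]] + uy * r_pick
      if (min_separation && length(prev_x)) {
        # 4 px clear gap so the 3x3 median/closing cleanup cannot bridge
        # two separate somata into one component
        dd <- sqrt((prev_x - x)^2 + (prev_y - y)^2)
        if (any(dd < prev_r + r_cell_px + 4)) next
      }
      out_x[i] <- x; out_y[i] <- y; out_d[i] <- d_um
      out_a[i] <- theta; out_r[i] <- r_pick * ps
      if (min_separation) {
        prev_x <- c(prev_x, x); prev_y <- c(prev_y, y)
        prev_r <- c(prev_r, r_cell_px)
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("placement error: retry budget exhausted for population '",
           spec$name, "'", call. = FALSE)
    }
  }
  out <- data.frame(population = spec$name, x_px = out_x, y_px = out_y,
                    diameter_um = out_d, true_angle_deg = out_a,
                    true_distance_um = out_r)
  for (m in marker_names()) out[[m]] <- m %in% spec$markers
  out
}

#' Place every configured population and apply co-expression rules
#'
#' Samples all populations of a [section_config()] (sequentially, sharing
#' the separation constraint when `min_separation` is on) and then applies
#' each co-expression rule by flagging exactly `round(fraction * count)`
#' seeded-random cells of the target population with the extra marker.
#'
#' @param config a [section_config()].
#' @param geometry matching [make_section_geometry()] output.
#' @param seed overrides `config$seed` when given.
#' @param count_dispersion if `TRUE`, each population's cell count for this
#'   section is drawn from a Poisson with the configured count as mean
#'   (sections of a real animal vary); `FALSE` (default) places exactly the
#'   configured counts.
#' @return ground-truth data frame (one row per cell, `id` column first).
#' @export
sample_section_cells <- function(config, geometry, seed = NULL,
                                 count_dispersion = FALSE) {
  seed <- if (is.null(seed)) config$seed else seed
  geometry$fit_map <- placement_fit_map(geometry)
  with_seed(seed, {
    cells <- NULL
    for (spec in config$populations) {
      if (count_dispersion) spec$count <- stats::rpois(1, spec$count)
      new <- sample_population_impl(spec, geometry,
                                    min_separation = config$min_separation,
                                    existing = cells, retry_budget = 100L)
      cells <- if (is.null(cells)) new else rbind(cells, new)
    }
    for (rule in config$coexpression) {
      sel <- which(cells$population == rule$population)
      k <- round(rule$fraction * length(sel))
      if (k > 0) {
        flag <- sample(sel, k)
        cells[[rule$marker]][flag] <- TRUE
      }
    }
    cells <- cbind(id = seq_len(nrow(cells)), cells)
    cells
  })
}
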