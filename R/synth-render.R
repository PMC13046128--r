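# Rendering of synthetic 4-channel z-stacks and fixture I/O.

# Linear indices of the pixels inside a disk of the given centre/radius.
disk_indices <- function(h, w, x, y, radius_px) {
  x0 <- max(1L, floor(x - radius_px)); x1 <- min(w, ceiling(x + radius_px))
  y0 <- max(1L, floor(y - radius_px)); y1 <- min(h, ceiling(y + radius_px))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx2 <- matrix((xs - x)^2, length(ys), length(xs), byrow = TRUE)
  dy2 <- matrix((ys - y)^2, length(ys), length(xs))
  inside <- which((dx2 + dy2) <= radius_px^2)
  ry <- ((inside - 1L) %% length(ys))
  rx <- ((inside - 1L) %/% length(ys))
  (x0 + rx - 1L) * h + (y0 + ry)
}

#' Render a synthetic four-channel z-stack
#'
#' Every ground-truth cell becomes a uniform-intensity disk (its configured
#' diameter) added to each channel whose marker flag it carries, with the
#' amplitude split across z-planes by the configured weights. Each plane of
#' each channel receives a constant background, a smooth diagonal intensity
#' ramp and independent Gaussian pixel noise, and is rounded and clipped to
#' the unsigned 16-bit range. Uniform disks (rather than point-spread
#' blobs) keep the thresholded particle area analytically predictable.
#'
#' @param cells ground-truth data frame from [sample_section_cells()].
#' @param geometry matching [make_section_geometry()] output.
#' @param config the [section_config()]; `config$seed` (offset) drives the
#'   noise, so identical configs render bit-identical stacks.
#' @return named list of [channel_stack()]s, one per marker, plus the
#'   ground truth as attribute `"truth"`.
#' @export
render_section <- function(cells, geometry, config) {
  h <- config$image_size[1]; w <- config$image_size[2]
  nz <- config$n_slices
  ps <- config$pixel_size
  ramp <- config$gradient_amplitude *
    (matrix(seq_len(w), h, w, byrow = TRUE) / w +
       matrix(seq_len(h), h, w) / h) / 2
  base <- config$background + ramp
  # linear pixel indices of every cell's disk, computed once
  disk_idx <- lapply(seq_len(nrow(cells)), function(i) {
    disk_indices(h, w, cells$x_px[i], cells$y_px[i],
                 cells$diameter_um[i] / 2 / ps)
  })
  stacks <- vector("list", length(marker_names()))
  names(stacks) <- marker_names()
  with_seed(config$seed + 5e8, {
    for (m in marker_names()) {
      vox <- array(base, dim = c(h, w, nz))
      flagged <- which(cells[[m]])
      for (z in seq_len(nz)) {
        amp <- config$cell_amplitude * config$z_weights[z]
        off <- (z - 1L) * h * w
        for (i in flagged) {
          idx <- disk_idx[[i]] + off
          vox[idx] <- vox[idx] + amp
        }
      }
      if (config$noise_sd > 0) {
        vox <- vox + stats::rnorm(length(vox), 0, config$noise_sd)
      }
      vox <- round(vox)
      vox[vox < 0] <- 0
      vox[vox > 65535] <- 65535
      stacks[[m]] <- channel_stack(vox, ps, marker = m)
    }
  })
  attr(stacks, "truth") <- cells
  stacks
}

#' Generate a complete synthetic section
#'
#' Convenience wrapper: geometry, ground-truth placement and rendering in
#' one call.
#'
#' @param config a [section_config()].
#' @param seed overrides `config$seed` for placement and noise.
#' @return list with `stacks`, `geometry`, `truth`.
#' @export
simulate_section <- function(config = section_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  geometry <- make_section_geometry(config)
  truth <- sample_section_cells(config, geometry)
  stacks <- render_section(truth, geometry, config)
  list(stacks = stacks, geometry = geometry, truth = truth)
}

#' Write a synthetic section to disk
#'
#' One multi-page 16-bit TIFF per channel, the gray-matter and canal masks
#' as single-page TIFFs, the ground truth as CSV and the scalar
#' configuration as a flat `key = value` text file. Read-back with
#' [read_fixture()] reproduces the written arrays bit-exactly.
#'
#' @param stacks named list of [channel_stack()]s from [render_section()].
#' @param truth ground-truth data frame.
#' @param directory existing output directory.
#' @param geometry the matching [section_geometry()].
#' @param config optional [section_config()] to record.
#' @return the directory, invisibly.
#' @export
write_fixture <- function(stacks, truth, directory, geometry,
                          config = NULL) {
  if (!dir.exists(directory)) {
    stop("output directory does not exist: ", directory, call. = FALSE)
  }
  for (m in names(stacks)) {
    v <- stacks[[m]]$voxels
    pages <- lapply(seq_len(dim(v)[3]), function(z) v[, , z] / 65535)
    tiff::writeTIFF(pages, file.path(directory, paste0(m, ".tif")),
                    bits.per.sample = 16L, reduce = FALSE)
  }
  tiff::writeTIFF(geometry$gray_mask, file.path(directory, "gray_mask.tif"),
                  bits.per.sample = 8L)
  tiff::writeTIFF(geometry$canal_mask, file.path(directory, "canal_mask.tif"),
                  bits.per.sample = 8L)
  utils::write.csv(truth, file.path(directory, "truth.csv"),
                   row.names = FALSE)
  meta <- c(pixel_size = stacks[[1]]$pixel_size,
            dorsal_up = as.integer(geometry$dorsal_up),
            canal_x = geometry$canal_centroid[[1]],
            canal_y = geometry$canal_centroid[[2]])
  if (!is.null(config)) {
    meta <- c(meta, n_slices = config$n_slices, seed = config$seed,
              background = config$background, noise_sd = config$noise_sd,
              cell_amplitude = config$cell_amplitude)
  }
  writeLines(paste(names(meta), unname(meta), sep = " = "),
             file.path(directory, "config.txt"))
  invisible(directory)
}

#' Read a synthetic section fixture back from disk
#'
#' @param directory directory written by [write_fixture()].
#' @return list with `stacks` (named [channel_stack()]s), `geometry` and
#'   `truth`.
#' @export
read_fixture <- function(directory) {
  cfg_lines <- readLines(file.path(directory, "config.txt"))
  kv <- strsplit(cfg_lines, " = ", fixed = TRUE)
  meta <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                          vapply(kv, `[`, "", 1))
  ps <- meta[["pixel_size"]]
  stacks <- list()
  for (m in marker_names()) {
    f <- file.path(directory, paste0(m, ".tif"))
    if (!file.exists(f)) next
    pages <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    vox <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) vox[, , z] <- pages[[z]]
    stacks[[m]] <- channel_stack(vox, ps, marker = m)
  }
  gray <- tiff::readTIFF(file.path(directory, "gray_mask.tif"), as.is = TRUE)
  canal <- tiff::readTIFF(file.path(directory, "canal_mask.tif"),
                          as.is = TRUE)
  geometry <- section_geometry(
    gray != 0, canal != 0,
    canal_centroid = c(x = meta[["canal_x"]], y = meta[["canal_y"]]),
    dorsal_up = meta[["dorsal_up"]] == 1, pixel_size = ps)
  truth <- utils::read.csv(file.path(directory, "truth.csv"))
  list(stacks = stacks, geometry = geometry, truth = truth)
}
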