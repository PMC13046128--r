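# Synthetic-section generator: geometry, placement, rendering, fixtures.

test_that("gray matter is mirror symmetric with the canal on the midline", {
  geom <- make_section_geometry(section_config())
  expect_equal(geom$gray_mask, geom$gray_mask[, rev(seq_len(ncol(geom$gray_mask)))])
  w <- ncol(geom$gray_mask)
  expect_lt(abs(roi_centroid(geom$canal_mask)[["x"]] - (w + 1) / 2), 0.5)
  expect_true(all(geom$gray_mask[geom$canal_mask == 1] == 1))
  expect_gt(sum(geom$gray_mask), sum(geom$canal_mask))
})

test_that("an oversized canal is a configuration error", {
  expect_error(make_section_geometry(section_config(canal_radius_um = 200)),
               "configuration error")
})

test_that("population sampling respects counts, bounds and determinism", {
  cfg <- tiny_config(seed = 5)
  geom <- make_section_geometry(cfg)
  spec0 <- population_spec("none", "ChAT", 0, c(10, 20))
  expect_equal(nrow(sample_population(spec0, geom, seed = 1)), 0)
  spec <- cfg$populations$gad
  a <- sample_population(spec, geom, seed = 11)
  b <- sample_population(spec, geom, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), spec$count)
  expect_true(all(a$diameter_um >= spec$diameter_um[1] &
                    a$diameter_um <= spec$diameter_um[2]))
  # every centroid inside the gray matter and outside the canal
  for (i in seq_len(nrow(a))) {
    expect_equal(geom$gray_mask[round(a$y_px[i]), round(a$x_px[i])], 1)
    expect_equal(geom$canal_mask[round(a$y_px[i]), round(a$x_px[i])], 0)
  }
})

test_that("sampled angles recover the configured von Mises mean", {
  cfg <- tiny_config()
  geom <- make_section_geometry(cfg)
  spec <- population_spec("vm", "GAD67", 500, c(10, 14),
                          angular = list(kind = "vonmises", mu_deg = 315,
                                         kappa = 2))
  cells <- sample_population(spec, geom, seed = 3, min_separation = FALSE)
  expect_lt(abs(((circular_mean(cells$true_angle_deg) - 315 + 180) %% 360) - 180),
            3)
})

test_that("placement error is raised when the mask cannot hold the cells", {
  cfg <- tiny_config()
  geom <- make_section_geometry(cfg)
  spec <- population_spec("too_many", "ChAT", 2000, c(27, 36))
  expect_error(sample_population(spec, geom, seed = 1, min_separation = TRUE),
               "placement error")
})

test_that("co-expression bookkeeping is exact", {
  cfg <- tiny_config(seed = 9)
  geom <- make_section_geometry(cfg)
  truth <- sample_section_cells(cfg, geom)
  n_parv <- sum(truth$population == "parv")
  expect_equal(sum(truth$Parvalbumin & truth$GAD67), round(0.5 * n_parv))
  expect_equal(sum(truth$Parvalbumin & truth$Calbindin), round(0.5 * n_parv))
  expect_true(all(rowSums(truth[, marker_names()]) >= 1))
})

test_that("true polar coordinates are consistent with the placement", {
  cfg <- tiny_config(seed = 10)
  geom <- make_section_geometry(cfg)
  truth <- sample_section_cells(cfg, geom)
  for (i in seq_len(nrow(truth))) {
    p <- polar_coords(c(truth$x_px[i], truth$y_px[i]), geom$canal_centroid,
                      geom$pixel_size, geom$dorsal_up)
    expect_equal(p$angle_deg, truth$true_angle_deg[i], tolerance = 1e-6)
    expect_equal(p$distance_um, truth$true_distance_um[i], tolerance = 1e-6)
  }
})

test_that("rendered sections are deterministic and 16-bit bounded", {
  cfg <- tiny_config(seed = 21, noise_sd = 800)
  a <- simulate_section(cfg)
  b <- simulate_section(cfg)
  expect_identical(a$stacks$ChAT$voxels, b$stacks$ChAT$voxels)
  expect_identical(a$truth, b$truth)
  v <- a$stacks$GAD67$voxels
  expect_true(all(v >= 0 & v <= 65535))
  expect_true(all(v == round(v)))
  expect_equal(dim(v)[3], cfg$n_slices)
})

test_that("cells appear only in the channels whose flag they carry", {
  cfg <- tiny_config(seed = 2)
  cfg$populations <- list(
    solo = population_spec("solo", "ChAT", 1, c(30, 30),
                           radial = list(kind = "beta", shape1 = 5,
                                         shape2 = 2)))
  cfg$coexpression <- list()
  sec <- simulate_section(cfg)
  chat_seg <- segment_channel(sec$stacks$ChAT, sec$geometry)
  cells <- find_particles(chat_seg$mask, cfg$pixel_size, NULL)
  expect_equal(nrow(cells), 1)
  # GAD channel: nothing above background anywhere near the cell
  gad_proj <- max_project(sec$stacks$GAD67)
  px <- attr(cells, "pixels")[[1]]
  expect_lt(max(gad_proj[px]), cfg$background + cfg$gradient_amplitude + 1)
})

test_that("thresholded disk areas match pi r^2 within rasterisation error", {
  cfg <- tiny_config()
  ps <- cfg$pixel_size
  for (d in c(10, 16, 24, 32, 40)) {
    cfg2 <- tiny_config(seed = d)
    cfg2$populations <- list(
      solo = population_spec("solo", "ChAT", 1, c(d, d),
                             radial = list(kind = "beta", shape1 = 3,
                                           shape2 = 3)))
    cfg2$coexpression <- list()
    sec <- simulate_section(cfg2)
    seg <- segment_channel(sec$stacks$ChAT, sec$geometry)
    cells <- find_particles(seg$mask, ps, NULL)
    expect_equal(nrow(cells), 1)
    expect_lt(abs(cells$area_um2 - pi * (d / 2)^2) / (pi * (d / 2)^2), 0.10)
  }
})

test_that("fixtures round-trip bit-exactly through disk", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 31, noise_sd = 500)
  sec <- simulate_section(cfg)
  write_fixture(sec$stacks, sec$truth, dir, sec$geometry, cfg)
  back <- read_fixture(dir)
  for (m in marker_names()) {
    expect_identical(back$stacks[[m]]$voxels + 0, sec$stacks[[m]]$voxels)
  }
  expect_equal(back$geometry$gray_mask, sec$geometry$gray_mask)
  expect_equal(back$geometry$canal_centroid, sec$geometry$canal_centroid,
               tolerance = 1e-9)
  expect_equal(nrow(back$truth), nrow(sec$truth))
  expect_equal(back$truth$diameter_um, sec$truth$diameter_um)
  expect_error(write_fixture(sec$stacks, sec$truth,
                             file.path(dir, "missing", "sub"),
                             sec$geometry), "directory")
})
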