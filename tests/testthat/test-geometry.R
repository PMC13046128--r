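# Polar mapping, laterality mirroring, distance normalisation.

test_that("ROI centroid equals the mean over an explicit pixel loop", {
  disk <- raster_disk(41, 41, 21, 21, 8)
  expect_equal(unname(roi_centroid(disk)), c(21, 21), tolerance = 0.5)
  single <- matrix(0, 10, 10); single[3, 7] <- 1
  expect_equal(unname(roi_centroid(single)), c(7, 3))
  set.seed(4)
  blob <- matrix(rbinom(100, 1, 0.3), 10, 10)
  cx <- 0; cy <- 0; n <- 0
  for (y in 1:10) for (x in 1:10) if (blob[y, x] == 1) {
    cx <- cx + x; cy <- cy + y; n <- n + 1
  }
  expect_equal(unname(roi_centroid(blob)), c(cx / n, cy / n))
  expect_error(roi_centroid(matrix(0, 3, 3)), "empty")
})

test_that("polar coordinates follow the 0-right / 90-dorsal convention", {
  canal <- c(100, 100)
  up <- polar_coords(c(100, 60), canal, 1, dorsal_up = TRUE)
  expect_equal(up$angle_deg, 90)
  expect_equal(up$distance_um, 40)
  expect_equal(polar_coords(c(140, 100), canal, 1)$angle_deg, 0)
  expect_equal(polar_coords(c(100, 140), canal, 1)$angle_deg, 270)
  expect_equal(polar_coords(c(103, 104), canal, 1)$distance_um, 5)
  down <- polar_coords(c(100, 60), canal, 1, dorsal_up = FALSE)
  expect_equal(down$angle_deg, 270)
  expect_equal(polar_coords(c(103, 104), canal, 2)$distance_um, 10)
  expect_error(polar_coords(canal, canal, 1), "undefined")
})

test_that("angles are translation invariant and 90-degree equivariant", {
  set.seed(5)
  for (i in 1:10) {
    canal <- runif(2, 50, 60)
    cell <- canal + runif(2, -20, 20)
    a0 <- polar_coords(cell, canal, 1)
    shift <- runif(2, -5, 5)
    a1 <- polar_coords(cell + shift, canal + shift, 1)
    expect_equal(a1$angle_deg, a0$angle_deg, tolerance = 1e-9)
    expect_equal(a1$distance_um, a0$distance_um, tolerance = 1e-9)
    # rotate the offset by +90 deg in image coordinates (dorsal_up):
    # (dx, dy) -> (dy, -dx) adds 90 to the angle
    d <- cell - canal
    rot <- canal + c(d[2], -d[1])
    a2 <- polar_coords(rot, canal, 1)
    expect_equal(a2$angle_deg, (a0$angle_deg + 90) %% 360, tolerance = 1e-9)
  }
})

test_that("laterality mirror follows theta' = 180 - theta on the left side", {
  expect_equal(mirror_left_to_right(135), 45)
  expect_equal(mirror_left_to_right(45), 45)
  expect_equal(mirror_left_to_right(225), 315)
  expect_equal(mirror_left_to_right(c(90, 270)), c(90, 270))  # boundaries
  theta <- seq(0, 359.5, by = 0.5)
  m <- mirror_left_to_right(theta)
  expect_equal(mirror_left_to_right(m), m)            # idempotent
  expect_equal(sin(m * pi / 180), sin(theta * pi / 180), tolerance = 1e-12)
  expect_true(all(m <= 90 | m >= 270))
})

test_that("radial-fraction normalisation is bounded and zero at the canal", {
  cfg <- tiny_config(seed = 2)
  geom <- make_section_geometry(cfg)
  expect_equal(normalise_distance(geom$canal_centroid, geom), 0)
  truth <- sample_section_cells(cfg, geom)
  v <- mapply(function(x, y) normalise_distance(c(x, y), geom),
              truth$x_px, truth$y_px)
  expect_true(all(v >= 0 & v <= 1))
  expect_error(normalise_distance(c(2, 2), geom), "outside")
})

test_that("radial fraction increases monotonically along rays", {
  mask <- raster_disk(201, 201, 101, 101, 90)
  canal <- raster_disk(201, 201, 101, 101, 5)
  geom <- section_geometry(mask, canal)
  for (ang in c(10, 100, 200, 300)) {
    r <- seq(10, 85, by = 5)
    pts_x <- 101 + r * cos(ang * pi / 180)
    pts_y <- 101 - r * sin(ang * pi / 180)
    v <- mapply(function(x, y) normalise_distance(c(x, y), geom),
                pts_x, pts_y)
    expect_true(all(diff(v) > 0))
  }
  # circular mask: boundary point along a ray normalises to ~1
  v_edge <- normalise_distance(c(101 + 89, 101), geom)
  expect_gt(v_edge, 0.97)
})

test_that("edge-map variants agree with the distance transform", {
  mask <- raster_disk(101, 101, 51, 51, 40)
  canal <- raster_disk(101, 101, 51, 51, 4)
  geom <- with_edge_map(section_geometry(mask, canal))
  # deepest pixel of a disk mask is its centre: edge_map -> 1
  expect_equal(normalise_distance(c(51, 51), geom, "edge_map"), 1,
               tolerance = 0.02)
  v <- normalise_distance(c(71, 51), geom, "canal_over_depthmax")
  expect_equal(v, 20 / max(geom$edge_map), tolerance = 0.02)
})

test_that("polar pipeline columns are mutually consistent", {
  sec <- simulate_section(tiny_config(seed = 8))
  cells <- process_section(sec$stacks, sec$geometry)
  expect_true(all(cells$angle_mirrored_deg ==
                    mirror_left_to_right(cells$angle_deg)))
  expect_true(all(cells$norm_distance >= 0 & cells$norm_distance <= 1))
  d <- sqrt((cells$x - sec$geometry$canal_centroid[[1]])^2 +
              (cells$y - sec$geometry$canal_centroid[[2]])^2)
  expect_equal(cells$distance_um, d * sec$geometry$pixel_size,
               tolerance = 1e-9)
})
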