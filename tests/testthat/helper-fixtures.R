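# Shared fixtures and independent oracles for the test suite.

# A scaled-down section (320 px, small counts) for fast unit tests; the
# full-size default config is reserved for the end-to-end recovery tests.
tiny_config <- function(seed = 1, noise_sd = 0, ...) {
  section_config(
    image_size = c(320, 320),
    gray_matter = list(
      band = list(center = c(0, 0), semi = c(120, 70), rot_deg = 0),
      ventral = list(center = c(60, -65), semi = c(65, 85), rot_deg = -20),
      dorsal = list(center = c(45, 80), semi = c(45, 75), rot_deg = 15)),
    canal_radius_um = 10,
    populations = list(
      chat_motor = population_spec(
        "chat_motor", "ChAT", 6, c(27, 36),
        angular = list(kind = "vonmises", mu_deg = c(315, 225), kappa = 3),
        radial = list(kind = "beta", shape1 = 4, shape2 = 1.6)),
      chat_inter = population_spec(
        "chat_inter", "ChAT", 4, c(12, 18.5),
        radial = list(kind = "beta", shape1 = 1.5, shape2 = 4.5)),
      calb = population_spec("calb", "Calbindin", 6, c(11, 21)),
      parv = population_spec(
        "parv", "Parvalbumin", 6, c(11, 19),
        angular = list(kind = "vonmises", mu_deg = c(15, 165), kappa = 2)),
      gad = population_spec("gad", "GAD67", 10, c(10, 18))),
    coexpression = list(
      list(population = "parv", marker = "GAD67", fraction = 0.5),
      list(population = "parv", marker = "Calbindin", fraction = 0.5)),
    min_separation = TRUE,
    noise_sd = noise_sd,
    seed = seed, ...)
}

# Rasterise a disk as a binary matrix (independent of the package's
# renderer).
raster_disk <- function(h, w, cx, cy, r_px) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  ((xs - cx)^2 + (ys - cy)^2 <= r_px^2) * 1
}

# Brute-force maximum-entropy threshold: independent histogramming and
# entropy evaluation over all 256 candidate cuts.
oracle_max_entropy <- function(vals, n_bins = 256L) {
  lo <- min(vals); hi <- max(vals)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- pmin(pmax(findInterval(vals, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  p <- tabulate(idx, nbins = n_bins) / length(vals)
  best_obj <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1L)) {
    pb <- p[1:t]; pf <- p[(t + 1L):n_bins]
    Pb <- sum(pb); Pf <- sum(pf)
    Hb <- if (Pb > 0) {
      q <- pb[pb > 0] / Pb; -sum(q * log(q))
    } else 0
    Hf <- if (Pf > 0) {
      q <- pf[pf > 0] / Pf; -sum(q * log(q))
    } else 0
    if (Hb + Hf > best_obj + 1e-12) { best_obj <- Hb + Hf; best_t <- t }
  }
  breaks[best_t + 1L]
}

# Naive mean-arc-distance objective for the circular median.
oracle_median_objective <- function(angles, phi) {
  sapply(phi, function(p) {
    d <- abs((angles - p) %% 360)
    mean(pmin(d, 360 - d))
  })
}

# Independent Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Nearest ground-truth centroid distance for every recovered cell.
centroid_errors <- function(cells, truth) {
  vapply(seq_len(nrow(cells)), function(i) {
    t2 <- truth[truth[[cells$marker[i]]], , drop = FALSE]
    if (!nrow(t2)) return(Inf)
    min(sqrt((t2$x_px - cells$x[i])^2 + (t2$y_px - cells$y[i])^2))
  }, numeric(1))
}
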