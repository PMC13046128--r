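# End-to-end orchestration: per-section segmentation and measurement,
# study-level aggregation, and the statistics layer.

#' Cell classes reported by the study
#'
#' The nine classes analysed per section: the four single markers, the two
#' ChAT size subclasses, and the three double-positive subsets (anchored on
#' the first-named marker).
#'
#' @return character vector of class labels.
#' @export
cell_classes <- function() {
  c("ChAT", "ChAT_interneuron", "ChAT_motor_neuron", "GAD67",
    "Calbindin", "Parvalbumin", "Parvalbumin_Calbindin",
    "Parvalbumin_GAD67", "ChAT_GAD67")
}

#' Process one section's four channels into a cell table
#'
#' Runs the segmentation chain per channel (projection, masking,
#' rolling-ball background subtraction, maximum-entropy threshold, binary
#' cleanup), extracts size-filtered particles per marker, classifies ChAT
#' cells into size subclasses, computes double-positive overlap fractions
#' (ChAT-in-GAD67, Parvalbumin-in-GAD67, Parvalbumin-in-Calbindin), and
#' maps every cell to canal-referenced polar coordinates with laterality
#' mirroring and normalised radial distance. Image measurements never see
#' sample metadata, so processing is blind to genotype by construction.
#'
#' @param stacks named list of [channel_stack()]s (the four markers).
#' @param geometry a [section_geometry()].
#' @param windows named list of [size_window()]s per marker.
#' @param coloc_cutoff double-positive overlap cutoff (default 0.20).
#' @param ball_radius_px rolling-ball radius in pixels (default 20).
#' @param norm_variant distance-normalisation variant
#'   (see [normalise_distance()]).
#' @return data frame, one row per detected cell, with centroid, area,
#'   size class, raw and mirrored angle, distance and normalised distance,
#'   overlap fractions and double-positive flags.
#' @export
process_section <- function(stacks, geometry,
                            windows = marker_size_windows(),
                            coloc_cutoff = 0.20, ball_radius_px = 20,
                            norm_variant = "radial_fraction") {
  ps <- stacks[[1]]$pixel_size
  seg <- lapply(stacks, segment_channel, geometry = geometry,
                ball_radius_px = ball_radius_px)
  per_marker <- list()
  for (m in names(stacks)) {
    cells <- find_particles(seg[[m]]$mask, ps, windows[[m]])
    px <- attr(cells, "pixels")
    if (m == "ChAT") {
      cells$size_class <- if (nrow(cells)) classify_chat_size(cells$area_um2)
                          else character(0)
    } else {
      cells$size_class <- rep(NA_character_, nrow(cells))
    }
    # overlap fractions against the partner channels used downstream
    partners <- switch(m, ChAT = "GAD67",
                       Parvalbumin = c("GAD67", "Calbindin"), character(0))
    for (b in partners) {
      frac <- vapply(px, overlap_fraction, numeric(1),
                     other_binary = seg[[b]]$mask)
      cells[[paste0("coexpr_", b)]] <- frac
      cells[[paste0("dp_", b)]] <- frac >= coloc_cutoff
    }
    per_marker[[m]] <- cells
  }
  all_cols <- unique(unlist(lapply(per_marker, names)))
  per_marker <- lapply(per_marker, function(d) {
    for (cc in setdiff(all_cols, names(d))) {
      d[[cc]] <- if (startsWith(cc, "dp_")) rep(NA, nrow(d))
                 else rep(NA_real_, nrow(d))
    }
    d[all_cols]
  })
  cells <- do.call(rbind, per_marker)
  rownames(cells) <- NULL
  if (nrow(cells)) {
    pol <- mapply(function(x, y) {
      p <- polar_coords(c(x, y), geometry$canal_centroid, ps,
                        geometry$dorsal_up)
      c(p$distance_um, p$angle_deg)
    }, cells$x, cells$y)
    cells$distance_um <- pol[1, ]
    cells$angle_deg <- pol[2, ]
    cells$angle_mirrored_deg <- mirror_left_to_right(cells$angle_deg)
    cells$norm_distance <- mapply(function(x, y) {
      normalise_distance(c(x, y), geometry, norm_variant)
    }, cells$x, cells$y)
  } else {
    cells$distance_um <- numeric(0)
    cells$angle_deg <- numeric(0)
    cells$angle_mirrored_deg <- numeric(0)
    cells$norm_distance <- numeric(0)
  }
  attr(cells, "pixels") <- NULL
  cells
}

# Membership of a cell-table row in a named class.
class_members <- function(cells, class) {
  switch(class,
    ChAT = cells$marker == "ChAT",
    ChAT_interneuron = cells$marker == "ChAT" &
      cells$size_class == "interneuron",
    ChAT_motor_neuron = cells$marker == "ChAT" &
      cells$size_class == "motor_neuron",
    GAD67 = cells$marker == "GAD67",
    Calbindin = cells$marker == "Calbindin",
    Parvalbumin = cells$marker == "Parvalbumin",
    Parvalbumin_Calbindin = cells$marker == "Parvalbumin" &
      !is.na(cells$dp_Calbindin) & cells$dp_Calbindin,
    Parvalbumin_GAD67 = cells$marker == "Parvalbumin" &
      !is.na(cells$dp_GAD67) & cells$dp_GAD67,
    ChAT_GAD67 = cells$marker == "ChAT" &
      !is.na(cells$dp_GAD67) & cells$dp_GAD67,
    stop("unknown cell class: ", class, call. = FALSE))
}

# Ground-truth class membership on a truth table (diameter splits ChAT).
truth_class_members <- function(truth, class) {
  switch(class,
    ChAT = truth$ChAT,
    ChAT_interneuron = truth$ChAT & truth$diameter_um < 25,
    ChAT_motor_neuron = truth$ChAT & truth$diameter_um >= 25,
    GAD67 = truth$GAD67,
    Calbindin = truth$Calbindin,
    Parvalbumin = truth$Parvalbumin,
    Parvalbumin_Calbindin = truth$Parvalbumin & truth$Calbindin,
    Parvalbumin_GAD67 = truth$Parvalbumin & truth$GAD67,
    ChAT_GAD67 = truth$ChAT & truth$GAD67,
    stop("unknown cell class: ", class, call. = FALSE))
}

#' Build a synthetic study
#'
#' Generates a full multi-animal study: by default 4 genotypes x 3 animals
#' x 8 sections (two per lumbar level L3-L6). Each section gets its own
#' deterministic child seed. An optional angular effect shifts the von
#' Mises component means of one population in one genotype, emulating a
#' genotype-dependent displacement.
#'
#' With `render = TRUE` every section is rendered and pushed through the
#' image pipeline ([process_section()]); with `render = FALSE` the cell
#' table is taken from the generator's ground truth (marker flags,
#' diameters and exact polar coordinates), which exercises the statistics
#' layer at a fraction of the cost.
#'
#' @param config base [section_config()].
#' @param genotypes character vector of group labels.
#' @param n_animals animals per genotype.
#' @param n_sections sections per animal (8 expected; other values warn).
#' @param seed study master seed.
#' @param effect optional angular displacement injected into one genotype:
#'   `list(genotype =, shift_deg =, marker =)` shifts every von Mises
#'   population carrying that marker (or name a single population with
#'   `population =` instead of `marker =`). The shift acts on the mirrored
#'   scale.
#' @param render run the image pipeline (`TRUE`) or use ground truth.
#' @param count_dispersion draw per-section population counts from a
#'   Poisson around the configured means (default `TRUE`; real sections
#'   vary, and it gives the count statistics non-degenerate variance).
#' @param norm_variant distance-normalisation variant for both modes.
#' @return list with `cells` (pooled cell table with `genotype`, `animal`,
#'   `section` columns), `manifest`, `truth` (pooled ground-truth tables)
#'   and `truth_counts` (per animal x section x class ground-truth counts).
#' @export
simulate_study <- function(config = section_config(),
                           genotypes = c("+/+", "-/+", "+/Loa", "-/Loa"),
                           n_animals = 3, n_sections = 8, seed = 1,
                           effect = NULL, render = TRUE,
                           count_dispersion = TRUE,
                           norm_variant = "radial_fraction") {
  if (n_sections != 8) {
    warning("study design expects 8 sections per animal (two per lumbar ",
            "level L3-L6); got ", n_sections)
  }
  levels_lab <- rep(paste0("L", 3:6), length.out = n_sections)
  manifest <- expand.grid(section = seq_len(n_sections),
                          animal = seq_len(n_animals),
                          genotype = genotypes,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  manifest$level <- levels_lab[manifest$section]
  manifest$animal <- paste0(manifest$genotype, "#", manifest$animal)
  seeds <- derive_seeds(seed, nrow(manifest))
  geometry <- make_section_geometry(config)
  geometry$fit_map <- placement_fit_map(geometry)
  out <- vector("list", nrow(manifest))
  truth_counts <- list()
  truths <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i] %% 2147483647)
    if (!is.null(effect) && manifest$genotype[i] == effect$genotype) {
      targets <- if (!is.null(effect$marker)) {
        direct <- vapply(cfg$populations, function(p)
          effect$marker %in% p$markers, logical(1))
        via_coexpr <- names(cfg$populations) %in% unlist(lapply(
          cfg$coexpression, function(r)
            if (identical(r$marker, effect$marker)) r$population))
        names(cfg$populations)[direct | via_coexpr]
      } else effect$population
      if (length(targets) == 0L || any(!targets %in% names(cfg$populations))) {
        stop("effect refers to unknown population or marker", call. = FALSE)
      }
      for (tg in targets) {
        pop <- cfg$populations[[tg]]
        if (identical(pop$angular$kind, "vonmises")) {
          # shift on the mirrored (laterality-corrected) scale: left-side
          # mixture components move opposite to right-side ones, so the
          # fold displaces by the full shift instead of cancelling
          mu <- wrap360(pop$angular$mu_deg)
          left <- mu > 90 & mu < 270
          pop$angular$mu_deg <- mu + ifelse(left, -1, 1) * effect$shift_deg
          cfg$populations[[tg]] <- pop
        }
      }
    }
    # a jammed rejection-sampling packing is rare but possible under
    # Poisson count spikes; deterministically re-draw the section (up to
    # twice) before giving up, like re-cutting a failed section
    truth <- NULL
    for (attempt in 0:2) {
      truth <- tryCatch(
        sample_section_cells(cfg, geometry,
                             seed = (cfg$seed + attempt * 7717) %% 2147483647,
                             count_dispersion = count_dispersion),
        error = function(e) if (attempt == 2) stop(e) else NULL)
      if (!is.null(truth)) break
    }
    if (render) {
      stacks <- render_section(truth, geometry, cfg)
      cells <- process_section(stacks, geometry,
                               norm_variant = norm_variant)
    } else {
      cells <- truth_to_cells(truth, geometry, norm_variant)
    }
    if (nrow(cells)) {
      cells$genotype <- manifest$genotype[i]
      cells$animal <- manifest$animal[i]
      cells$section <- manifest$section[i]
      cells$level <- manifest$level[i]
    }
    out[[i]] <- cells
    tc <- vapply(cell_classes(), function(cl)
      sum(truth_class_members(truth, cl)), numeric(1))
    truth_counts[[i]] <- data.frame(genotype = manifest$genotype[i],
                                    animal = manifest$animal[i],
                                    section = manifest$section[i],
                                    class = cell_classes(), count = tc)
    truth$genotype <- manifest$genotype[i]
    truth$animal <- manifest$animal[i]
    truth$section <- manifest$section[i]
    truths[[i]] <- truth
  }
  list(cells = do.call(rbind, out), manifest = manifest,
       truth = do.call(rbind, truths),
       truth_counts = do.call(rbind, truth_counts), seed = seed,
       config = config)
}

# Expand a ground-truth table into the per-cell measurement table used by
# the statistics layer (bypassing the image pipeline).
truth_to_cells <- function(truth, geometry, norm_variant = "radial_fraction") {
  rows <- list()
  for (m in marker_names()) {
    sel <- truth[[m]]
    if (!any(sel)) next
    t2 <- truth[sel, ]
    cells <- data.frame(
      id = t2$id, marker = m, x = t2$x_px, y = t2$y_px,
      n_px = NA_integer_, area_um2 = diameter_to_area(t2$diameter_um),
      size_class = ifelse(m == "ChAT",
                          ifelse(t2$diameter_um < 25, "interneuron",
                                 "motor_neuron"), NA_character_))
    cells$coexpr_GAD67 <- as.numeric(t2$GAD67)
    cells$dp_GAD67 <- t2$GAD67
    cells$coexpr_Calbindin <- as.numeric(t2$Calbindin)
    cells$dp_Calbindin <- t2$Calbindin
    cells$distance_um <- t2$true_distance_um
    cells$angle_deg <- t2$true_angle_deg
    cells$angle_mirrored_deg <- mirror_left_to_right(t2$true_angle_deg)
    cells$norm_distance <- mapply(function(x, y) {
      normalise_distance(c(x, y), geometry, norm_variant)
    }, t2$x_px, t2$y_px)
    rows[[m]] <- cells
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rose-diagram bin percentages
#'
#' Equal-width angular bins over `[0, 360)`; bar lengths are the percentage
#' of cells per bin (distance information is ignored), summing to 100.
#'
#' @param angles numeric vector of angles in degrees (non-empty).
#' @param n_bins number of bins, at least 4 (default 36, i.e. 10-degree
#'   bins).
#' @return data frame with `bin_start`, `bin_end`, `percent`.
#' @export
rose_histogram <- function(angles, n_bins = 36) {
  if (length(angles) == 0L) stop("empty angle sample", call. = FALSE)
  if (n_bins < 4) stop("need at least 4 bins", call. = FALSE)
  angles <- wrap360(angles)
  width <- 360 / n_bins
  idx <- pmin(floor(angles / width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_start = (seq_len(n_bins) - 1L) * width,
             bin_end = seq_len(n_bins) * width,
             percent = 100 * counts / sum(counts))
}

#' Per-animal count table
#'
#' Sums each class's cells over every animal's sections (classes with no
#' cells are carried as zero, not dropped) and adds per-genotype mean and
#' standard deviation across animals.
#'
#' @param cells pooled cell table from [simulate_study()] /
#'   [process_section()] with `genotype`, `animal`, `section` columns.
#' @param classes class labels to tabulate (default [cell_classes()]).
#' @return list with `per_animal` (genotype, animal, class, count) and
#'   `per_genotype` (class, genotype, mean, sd, n_animals).
#' @export
summarize_counts <- function(cells, classes = cell_classes()) {
  animals <- unique(cells[, c("genotype", "animal")])
  if (nrow(animals) == 0L) stop("no animals in the cell table",
                                call. = FALSE)
  grid <- merge(animals, data.frame(class = classes), by = NULL)
  grid$count <- mapply(function(g, a, cl) {
    sub <- cells[cells$genotype == g & cells$animal == a, , drop = FALSE]
    sum(class_members(sub, cl))
  }, grid$genotype, grid$animal, grid$class)
  agg_mean <- stats::aggregate(count ~ class + genotype, grid, mean)
  agg_sd <- stats::aggregate(count ~ class + genotype, grid, stats::sd)
  agg_n <- stats::aggregate(count ~ class + genotype, grid, length)
  per_genotype <- data.frame(class = agg_mean$class,
                             genotype = agg_mean$genotype,
                             mean = agg_mean$count, sd = agg_sd$count,
                             n_animals = agg_n$count)
  list(per_animal = grid, per_genotype = per_genotype)
}

#' Statistics layer of a study
#'
#' For every cell class: one-way ANOVA on per-animal counts across
#' genotypes; nested one-way ANOVA (animals within genotype) on per-cell
#' normalised distances; the common circular-median test on mirrored
#' angles pooled per genotype; pairwise two-sample Kuiper post hoc tests
#' with Benjamini-Hochberg adjustment within the class's family of
#' genotype pairs; circular means, variances and mean-angle confidence
#' intervals per genotype; and rose-diagram bin tables. Classes lacking
#' the minimum group sizes are skipped for the affected test (recorded as
#' `NA`).
#'
#' @param cells pooled cell table with `genotype` and `animal` columns.
#' @param classes classes to analyse (default [cell_classes()]).
#' @param alpha significance level recorded in the bundle.
#' @param n_perm permutations for Kuiper p-values.
#' @param seed seed for the permutation tests (deterministic bundle).
#' @param rose_bins bins for the rose tables.
#' @param kuiper_method `"permutation"` or `"asymptotic"`.
#' @return list of class `"results_bundle"`: `counts`, `count_anova`,
#'   `distance_anova`, `circular_main`, `circular_pairwise`,
#'   `circular_summary`, `rose`, `settings`.
#' @export
analyze_cells <- function(cells, classes = cell_classes(), alpha = 0.05,
                          n_perm = 1000, seed = 1, rose_bins = 36,
                          kuiper_method = "permutation") {
  counts <- summarize_counts(cells, classes)
  genotypes <- unique(cells$genotype)
  count_anova <- list(); distance_anova <- list()
  circular_main <- list(); pairwise <- list(); summaries <- list()
  rose <- list()
  pair_grid <- if (length(genotypes) >= 2) utils::combn(genotypes, 2) else NULL
  seeds <- derive_seeds(seed, length(classes) * max(1, ncol(pair_grid)))
  si <- 0L
  for (cl in classes) {
    sub <- cells[class_members(cells, cl), , drop = FALSE]
    pa <- counts$per_animal[counts$per_animal$class == cl, ]
    groups <- split(pa$count, pa$genotype)
    count_anova[[cl]] <- tryCatch(
      c(one_way_anova(groups), list(class = cl)),
      error = function(e) list(F = NA, p_value = NA, class = cl,
                               note = conditionMessage(e)))
    distance_anova[[cl]] <- tryCatch(
      c(nested_anova(sub$norm_distance, sub$genotype, sub$animal),
        list(class = cl)),
      error = function(e) list(F = NA, p_value = NA, class = cl,
                               note = conditionMessage(e)))
    ang <- split(sub$angle_mirrored_deg, sub$genotype)
    circular_main[[cl]] <- tryCatch(
      c(unclass(common_median_test(ang)), list(class = cl)),
      error = function(e) list(statistic = NA, p_value = NA, class = cl,
                               note = conditionMessage(e)))
    for (g in genotypes) {
      a <- ang[[g]]
      if (is.null(a) || length(a) < 1) next
      ci <- tryCatch(mean_angle_ci(a), error = function(e) NULL)
      summaries[[paste(cl, g)]] <- data.frame(
        class = cl, genotype = g, n = length(a),
        circ_mean = tryCatch(circular_mean(a), error = function(e) NA),
        circ_variance = circular_variance(a),
        ci_lower = if (is.null(ci)) NA else ci$lower,
        ci_upper = if (is.null(ci)) NA else ci$upper)
      rose[[paste(cl, g)]] <- cbind(class = cl, genotype = g,
                                    rose_histogram(a, rose_bins))
    }
    if (!is.null(pair_grid)) {
      pv <- rep(NA_real_, ncol(pair_grid)); vv <- pv
      for (j in seq_len(ncol(pair_grid))) {
        si <- si + 1L
        g1 <- pair_grid[1, j]; g2 <- pair_grid[2, j]
        a <- ang[[g1]]; b <- ang[[g2]]
        if (is.null(a) || is.null(b) || length(a) < 5 || length(b) < 5) next
        kt <- kuiper_two_sample(a, b, n_perm = n_perm,
                                seed = as.integer(seeds[si] %% 2147483647),
                                method = kuiper_method)
        pv[j] <- kt$p_value; vv[j] <- kt$statistic
      }
      qv <- rep(NA_real_, length(pv))
      if (any(!is.na(pv))) qv[!is.na(pv)] <- bh_adjust(pv[!is.na(pv)])
      pairwise[[cl]] <- data.frame(class = cl, genotype_a = pair_grid[1, ],
                                   genotype_b = pair_grid[2, ],
                                   V = vv, p_value = pv, q_value = qv)
    }
  }
  structure(list(
    counts = counts,
    count_anova = do.call(rbind, lapply(count_anova, function(x)
      data.frame(class = x$class, F = x$F, p_value = x$p_value))),
    distance_anova = do.call(rbind, lapply(distance_anova, function(x)
      data.frame(class = x$class, F = x$F, p_value = x$p_value))),
    circular_main = do.call(rbind, lapply(circular_main, function(x)
      data.frame(class = x$class, statistic = x$statistic,
                 p_value = x$p_value))),
    circular_pairwise = do.call(rbind, pairwise),
    circular_summary = do.call(rbind, summaries),
    rose = do.call(rbind, rose),
    settings = list(alpha = alpha, n_perm = n_perm, seed = seed,
                    rose_bins = rose_bins)),
    class = "results_bundle")
}

#' Run a complete synthetic study
#'
#' [simulate_study()] followed by [analyze_cells()]; optionally writes the
#' bundle's tables as CSV files.
#'
#' @inheritParams simulate_study
#' @inheritParams analyze_cells
#' @param out_dir optional directory for CSV output
#'   (see [write_results_bundle()]).
#' @return the study list with an added `results` element.
#' @export
run_study <- function(config = section_config(),
                      genotypes = c("+/+", "-/+", "+/Loa", "-/Loa"),
                      n_animals = 3, n_sections = 8, seed = 1,
                      effect = NULL, render = TRUE, alpha = 0.05,
                      n_perm = 1000, out_dir = NULL,
                      kuiper_method = "permutation") {
  study <- simulate_study(config, genotypes, n_animals, n_sections, seed,
                          effect = effect, render = render)
  study$results <- analyze_cells(study$cells, alpha = alpha,
                                 n_perm = n_perm, seed = seed,
                                 kuiper_method = kuiper_method)
  if (!is.null(out_dir)) write_results_bundle(study$results, out_dir,
                                              cells = study$cells)
  study
}

#' Write a results bundle as CSV tables
#'
#' @param results a `"results_bundle"` from [analyze_cells()].
#' @param out_dir directory (created if missing).
#' @param cells optional per-cell table to include.
#' @return `out_dir`, invisibly.
#' @export
write_results_bundle <- function(results, out_dir, cells = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(results$counts$per_animal,
                   file.path(out_dir, "counts_per_animal.csv"),
                   row.names = FALSE)
  utils::write.csv(results$counts$per_genotype,
                   file.path(out_dir, "counts_per_genotype.csv"),
                   row.names = FALSE)
  utils::write.csv(results$count_anova,
                   file.path(out_dir, "count_anova.csv"), row.names = FALSE)
  utils::write.csv(results$distance_anova,
                   file.path(out_dir, "distance_anova.csv"),
                   row.names = FALSE)
  utils::write.csv(results$circular_main,
                   file.path(out_dir, "circular_main.csv"),
                   row.names = FALSE)
  if (!is.null(results$circular_pairwise)) {
    utils::write.csv(results$circular_pairwise,
                     file.path(out_dir, "circular_pairwise.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(results$circular_summary,
                   file.path(out_dir, "circular_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(results$rose, file.path(out_dir, "rose_bins.csv"),
                   row.names = FALSE)
  if (!is.null(cells)) {
    cells_out <- cells
    utils::write.csv(cells_out, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' Draw a rose diagram
#'
#' Base-graphics circular histogram of a rose-bin table; bar length is the
#' percentage of cells per angular bin.
#'
#' @param bins data frame from [rose_histogram()].
#' @param main plot title.
#' @export
plot_rose <- function(bins, main = "") {
  r <- sqrt(bins$percent / max(bins$percent, 1e-9))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (rad in sqrt(c(0.25, 0.5, 1))) {
    th <- seq(0, 2 * pi, length.out = 180)
    graphics::lines(rad * cos(th), rad * sin(th), col = "gray80")
  }
  for (i in seq_len(nrow(bins))) {
    th <- deg2rad(seq(bins$bin_start[i], bins$bin_end[i], length.out = 12))
    graphics::polygon(c(0, r[i] * cos(th), 0), c(0, r[i] * sin(th), 0),
                      col = grDevices::adjustcolor("steelblue", 0.7),
                      border = "white")
  }
  graphics::text(c(1.07, 0, -1.07, 0), c(0, 1.07, 0, -1.07),
                 c("0°", "90°", "180°", "270°"),
                 cex = 0.8)
  invisible(bins)
}
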