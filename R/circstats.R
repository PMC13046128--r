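# Circular statistics for cell-angle data.
#
# All user-facing interfaces take and return angles in degrees on [0, 360);
# radians are used internally only. Angle sets pooled per cell class x
# genotype are the unit of inference.

check_angles <- function(angles, min_n = 1L) {
  if (!is.numeric(angles) || length(angles) < min_n) {
    stop(sprintf("need at least %d finite angles", min_n), call. = FALSE)
  }
  if (any(!is.finite(angles))) stop("angles must be finite", call. = FALSE)
  wrap360(angles)
}

# Mean resultant length of a sample of angles in degrees.
resultant_length <- function(angles) {
  a <- deg2rad(angles)
  sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}

#' Circular mean of a sample of angles
#'
#' Direction of the mean resultant vector of a set of angles, i.e.
#' `atan2(mean(sin), mean(cos))` mapped to `[0, 360)`.
#'
#' @param angles numeric vector of angles in degrees.
#' @param eps smallest admissible mean resultant length; below this the mean
#'   direction is numerically undefined and an error is raised.
#' @return mean direction in degrees on `[0, 360)`.
#' @examples
#' circular_mean(c(10, 350)) # 0
#' circular_mean(c(0, 90))   # 45
#' @export
circular_mean <- function(angles, eps = 1e-9) {
  angles <- check_angles(angles)
  a <- deg2rad(angles)
  s <- mean(sin(a)); c <- mean(cos(a))
  if (sqrt(s^2 + c^2) <= eps) {
    stop("circular mean undefined: mean resultant length ~ 0", call. = FALSE)
  }
  wrap360(rad2deg(atan2(s, c)))
}

#' Circular variance of a sample of angles
#'
#' One minus the mean resultant length; 0 for identical angles, 1 for a
#' perfectly balanced (zero-resultant) sample. Unitless, in `[0, 1]`.
#'
#' @inheritParams circular_mean
#' @export
circular_variance <- function(angles) {
  angles <- check_angles(angles)
  1 - resultant_length(angles)
}

# Mean arc distance from each phi to every sample angle (the circular-
# median objective). Sorted-prefix-sum evaluation, O((n + k) log n) for k
# candidates: for a given phi, angles within the half-circle [phi,
# phi + 180) contribute their forward arc, the rest the backward arc; both
# partial sums come from prefix sums over the doubled sorted sample.
median_objective <- function(angles, phi) {
  x <- sort(wrap360(angles))
  n <- length(x)
  y <- c(x, x + 360)
  P <- c(0, cumsum(y))
  phi <- wrap360(phi)
  k <- findInterval(phi, x) + 1L          # first angle >= phi (doubled idx)
  m <- findInterval(phi + 180, y)         # last angle < phi + 180 (approx)
  m <- pmin(pmax(m, k - 1L), k + n - 1L)
  c1 <- m - k + 1L
  sum_in <- (P[m + 1L] - P[k]) - c1 * phi
  c2 <- n - c1
  sum_out <- c2 * (360 + phi) - (P[k + n] - P[m + 1L])
  (sum_in + sum_out) / n
}

#' Circular median of a sample of angles
#'
#' The direction minimising the mean arc distance to the sample. The
#' objective is piecewise linear with breakpoints at the data points and
#' their antipodes, so the minimum is found by evaluating those candidates
#' (plus midpoints of circularly adjacent data pairs, which resolve the flat
#' minima of even-sized samples). Ties are broken by the candidate closest
#' to the circular mean; if the sample is so symmetric that the mean is also
#' undefined, the median is reported as ambiguous.
#'
#' @inheritParams circular_mean
#' @param tol objective values within `tol` of the minimum count as tied.
#' @return median direction in degrees on `[0, 360)`.
#' @export
circular_median <- function(angles, tol = 1e-9) {
  angles <- check_angles(angles)
  srt <- sort(unique(wrap360(angles)))
  mids <- wrap360(srt + circ_diff_deg(c(srt[-1], srt[1]), srt) / 2)
  cand <- unique(c(srt, mids, wrap360(srt + 180)))
  obj <- median_objective(angles, cand)
  best <- cand[obj <= min(obj) + tol]
  if (length(best) == 1L) return(best)
  mu <- tryCatch(circular_mean(angles), error = function(e) NULL)
  if (is.null(mu)) {
    stop("circular median ambiguous: tied minimisers and undefined mean",
         call. = FALSE)
  }
  d <- arc_dist_deg(best, mu)
  best <- best[d == min(d)]
  min(best)
}

#' Multi-sample test for a common circular median
#'
#' Nonparametric k-sample test of equal circular medians (the circular
#' analogue of a Kruskal-Wallis test). All samples are pooled and the pooled
#' circular median is found; for each group, `m_i` counts the angles lying
#' in the half-circle clockwise of the pooled median (signed circular
#' difference < 0). With `N` total angles and `M = sum(m_i)`, the statistic
#'
#'   `P = N^2 / (M (N - M)) * sum(m_i^2 / n_i) - N M / (N - M)`
#'
#' is referred to a chi-squared distribution with `k - 1` degrees of
#' freedom.
#'
#' @param groups named list of numeric vectors of angles in degrees, one per
#'   group; each group needs at least 10 angles.
#' @return object of class `"circ_test"`: a list with `statistic`, `df`,
#'   `p_value`, `pooled_median`, per-group `n` and below-median counts `m`.
#' @export
common_median_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  groups <- lapply(groups, check_angles, min_n = 10L)
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  pooled <- unlist(groups, use.names = FALSE)
  med <- circular_median(pooled)
  m <- vapply(groups, function(g) sum(circ_diff_deg(g, med) < 0), numeric(1))
  N <- sum(n); M <- sum(m)
  if (M <= 0 || M >= N) {
    stop("degenerate partition: pooled median does not split the data",
         call. = FALSE)
  }
  on_median <- vapply(groups, function(g) all(arc_dist_deg(g, med) < 1e-12),
                      logical(1))
  if (any(on_median)) {
    stop("degenerate partition: a group lies entirely on the pooled median",
         call. = FALSE)
  }
  P <- N^2 / (M * (N - M)) * sum(m^2 / n) - N * M / (N - M)
  p <- stats::pchisq(P, df = k - 1, lower.tail = FALSE)
  structure(
    list(statistic = P, df = k - 1, p_value = p, pooled_median = med,
         n = n, m = m, method = "common circular median test"),
    class = "circ_test")
}

# Kuiper V between two samples of angles (degrees): the maximum spread of
# the difference of circular empirical distribution functions, evaluated
# after each tie group of the pooled sorted values (so identical multisets
# give V = 0). Rotation invariant by construction.
kuiper_statistic <- function(a, b) {
  na <- length(a); nb <- length(b)
  v <- c(a, b)
  ord <- order(v)
  lab <- c(rep(1L, na), rep(0L, nb))[ord]
  ends <- which(diff(v[ord]) > 0)
  ends <- c(ends, na + nb)
  ca <- cumsum(lab)[ends]
  d <- ca / na - (ends - ca) / nb
  max(d) - min(d)
}

# Upper tail of the asymptotic Kuiper distribution with Stephens' small-
# sample correction; `neff` is the effective sample size.
kuiper_pvalue_asymptotic <- function(V, neff) {
  lambda <- (sqrt(neff) + 0.155 + 0.24 / sqrt(neff)) * V
  if (lambda < 0.4) return(1)
  j <- seq_len(120)
  p <- 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kuiper test for circular data
#'
#' Rotation-invariant circular analogue of the two-sample
#' Kolmogorov-Smirnov test. The statistic is
#' `V = max(F_a - F_b) + max(F_b - F_a)` over the circular empirical
#' distribution functions of the two samples. The p-value is obtained by
#' label permutation (default), which is exact up to Monte-Carlo error, or
#' from the asymptotic Kuiper distribution with Stephens' correction.
#'
#' @param a,b numeric vectors of angles in degrees (each at least 5).
#' @param n_perm number of label permutations for the permutation p-value.
#' @param seed optional integer seed making the permutation p-value
#'   reproducible; the caller's RNG state is restored afterwards.
#' @param method `"permutation"` or `"asymptotic"`.
#' @return object of class `"circ_test"` with `statistic` (V), `p_value`,
#'   sample sizes and the method used.
#' @export
kuiper_two_sample <- function(a, b, n_perm = 10000, seed = NULL,
                              method = c("permutation", "asymptotic")) {
  method <- match.arg(method)
  a <- check_angles(a, 5L); b <- check_angles(b, 5L)
  na <- length(a); nb <- length(b)
  V <- kuiper_statistic(a, b)
  if (method == "asymptotic") {
    p <- kuiper_pvalue_asymptotic(V, na * nb / (na + nb))
  } else {
    pooled <- c(a, b)
    N <- na + nb
    ord <- order(pooled)
    ends <- c(which(diff(pooled[ord]) > 0), N)
    p <- with_seed(seed, {
      hits <- 0L
      for (i in seq_len(n_perm)) {
        lab <- integer(N)
        lab[sample.int(N, na)] <- 1L
        lab <- lab[ord]
        ca <- cumsum(lab)[ends]
        d <- ca / na - (ends - ca) / nb
        if (max(d) - min(d) >= V - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (n_perm + 1)
    })
  }
  structure(
    list(statistic = V, p_value = p, n = c(na, nb), method = method,
         test = "two-sample Kuiper test"),
    class = "circ_test")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values: sort ascending, set
#' `q_i = min_{j >= i} (p_j * m / j)` capped at 1, and return q-values in
#' the input order. Delegates to [stats::p.adjust()] after validating the
#' input range.
#'
#' @param p numeric vector of p-values, all in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0L) stop("need p-values", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Confidence interval for the circular mean
#'
#' Large-sample dispersion-based confidence interval for the mean
#' direction: with mean resultant length `R`, second trigonometric moment
#' about the mean `rho2`, and circular dispersion
#' `delta = (1 - rho2) / (2 R^2)`, the half-width is
#' `asin(z * sqrt(delta / n))`. The interval is undefined for samples too
#' dispersed for their size (when the arcsine argument exceeds 1, e.g.
#' near-uniform small samples).
#'
#' @inheritParams circular_mean
#' @param level confidence level, default 0.95.
#' @return list with `mean`, `lower`, `upper` (degrees, wrapped to
#'   `[0, 360)`) and `half_width` in degrees.
#' @export
mean_angle_ci <- function(angles, level = 0.95) {
  angles <- check_angles(angles)
  n <- length(angles)
  r <- resultant_length(angles)
  if (r <= 1e-9) {
    stop("confidence interval undefined: resultant too small for n",
         call. = FALSE)
  }
  mu <- circular_mean(angles)
  a <- deg2rad(angles - mu)
  rho2 <- mean(cos(2 * a))
  delta <- (1 - rho2) / (2 * r^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  arg <- z * sqrt(delta / n)
  if (arg > 1) {
    stop("confidence interval undefined: resultant too small for n",
         call. = FALSE)
  }
  half <- rad2deg(asin(arg))
  list(mean = mu, lower = wrap360(mu - half), upper = wrap360(mu + half),
       half_width = half)
}

#' @export
print.circ_test <- function(x, ...) {
  cat(if (!is.null(x$method) && x$method %in% c("permutation", "asymptotic"))
        x$test else x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 4),
      if (!is.null(x$df)) paste0("df = ", x$df) else "",
      " p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
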