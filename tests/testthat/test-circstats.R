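# Circular descriptive and inferential statistics.

test_that("circular mean and variance match symmetry cases", {
  expect_equal(circular_mean(c(10, 350)), 0)
  expect_equal(circular_mean(90), 90)
  expect_equal(circular_mean(c(0, 90)), 45)
  expect_equal(circular_variance(rep(123, 5)), 0)
  expect_equal(circular_variance(c(0, 90, 180, 270)), 1)
  expect_equal(circular_variance(c(0, 180)), 1)
  expect_error(circular_mean(c(0, 90, 180, 270)), "undefined")
})

test_that("circular median handles arc-ordered and wrap-around samples", {
  expect_equal(circular_median(c(10, 20, 30)), 20)
  expect_equal(circular_median(c(350, 0, 10)), 0)
  expect_error(circular_median(c(0, 90, 180, 270)), "ambiguous")
})

test_that("circular median equals exhaustive 0.1-degree grid minimisation", {
  set.seed(42)
  grid <- seq(0, 359.9, by = 0.1)
  for (rep in 1:8) {
    a <- runif(15, 0, 360)
    med <- circular_median(a)
    obj_grid <- oracle_median_objective(a, grid)
    best <- min(obj_grid)
    expect_lte(oracle_median_objective(a, med), best + 1e-9)
    # for odd continuous samples the minimiser is unique: angles agree
    expect_lt(min(abs(((grid[which.min(obj_grid)] - med + 180) %% 360) - 180)),
              0.11)
  }
})

test_that("fast median objective agrees with the naive evaluation", {
  set.seed(7)
  for (rep in 1:20) {
    a <- runif(sample(2:50, 1), 0, 360)
    phi <- runif(25, 0, 360)
    expect_equal(spinalpolar:::median_objective(a, phi),
                 oracle_median_objective(a, phi), tolerance = 1e-9)
  }
})

test_that("common-median test statistic follows its defining formula", {
  set.seed(1)
  g <- list(a = runif(30, 0, 120), b = runif(30, 40, 170),
            c = runif(30, 10, 140))
  res <- common_median_test(g)
  med <- circular_median(unlist(g))
  m <- vapply(g, function(x) {
    d <- (x - med) %% 360
    sum(d > 180)
  }, numeric(1))
  N <- 90; M <- sum(m)
  P <- N^2 / (M * (N - M)) * sum(m^2 / 30) - N * M / (N - M)
  expect_equal(res$statistic, P)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(P, 2, lower.tail = FALSE))
})

test_that("common-median test agrees with a permutation oracle", {
  set.seed(99)
  g <- list(a = c(rvonmises(25, 20, 1.5)), b = c(rvonmises(25, 60, 1.5)))
  res <- common_median_test(g)
  pooled <- unlist(g)
  stat_of <- function(lab) {
    common_median_test(split(pooled, lab))$statistic
  }
  lab0 <- rep(c("a", "b"), each = 25)
  perm <- replicate(2000, {
    tryCatch(stat_of(sample(lab0)), error = function(e) NA)
  })
  p_perm <- mean(perm >= res$statistic - 1e-12, na.rm = TRUE)
  # chi-squared p and permutation p agree within Monte-Carlo error
  expect_lt(abs(res$p_value - p_perm), 3.5 * sqrt(p_perm * (1 - p_perm) / 2000) + 0.02)
})

test_that("common-median test rejects strongly separated groups", {
  set.seed(5)
  hits <- 0
  for (i in 1:50) {
    a <- rvonmises(100, 0, 2)
    b <- rvonmises(100, 90, 2)
    if (common_median_test(list(a, b))$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("Kuiper test is zero for identical samples and rotation invariant", {
  set.seed(3)
  a <- runif(20, 0, 360)
  res <- kuiper_two_sample(a, a, n_perm = 200, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  b <- runif(25, 0, 360)
  v0 <- kuiper_two_sample(a, b, n_perm = 10, seed = 1)$statistic
  for (shift in c(13.7, 90, 215.2)) {
    v1 <- kuiper_two_sample((a + shift) %% 360, (b + shift) %% 360,
                            n_perm = 10, seed = 1)$statistic
    expect_equal(v1, v0, tolerance = 1e-12)
  }
})

test_that("Kuiper statistic matches a direct ECDF-difference evaluation", {
  set.seed(8)
  a <- runif(12, 0, 360); b <- runif(17, 0, 360)
  pts <- sort(c(a, b))
  d <- vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))
  expect_equal(kuiper_two_sample(a, b, n_perm = 10, seed = 1)$statistic,
               max(d) - min(d))
})

test_that("permutation and asymptotic Kuiper p-values broadly agree", {
  set.seed(21)
  a <- rvonmises(60, 0, 1); b <- rvonmises(60, 45, 1)
  p1 <- kuiper_two_sample(a, b, n_perm = 2000, seed = 2)$p_value
  p2 <- kuiper_two_sample(a, b, method = "asymptotic")$p_value
  expect_lt(abs(p1 - p2), 0.05)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  p <- runif(9)
  q <- bh_adjust(p)
  expect_equal(q, oracle_bh(p))
  expect_true(all(q >= p & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("mean-angle confidence interval behaves at the extremes", {
  res <- mean_angle_ci(rep(77, 20))
  expect_equal(res$mean, 77)
  expect_equal(res$half_width, 0)
  expect_error(mean_angle_ci(runif(8, 0, 360) * 0 + c(0, 90, 180, 270)),
               "undefined")
})

test_that("mean-angle CI attains nominal coverage for concentrated samples", {
  set.seed(31)
  cover <- 0
  n_rep <- 500
  for (i in seq_len(n_rep)) {
    a <- rvonmises(1000, 30, 4)
    ci <- mean_angle_ci(a)
    d_lo <- ((30 - ci$mean + 180) %% 360) - 180
    if (abs(d_lo) <= ci$half_width) cover <- cover + 1
  }
  expect_gte(cover / n_rep, 0.93)
  expect_lte(cover / n_rep, 0.97)
})

test_that("circular statistics are rotation equivariant", {
  set.seed(60)
  a <- rvonmises(40, 120, 2)
  b <- rvonmises(35, 150, 2)
  for (c_shift in c(30, 111.1, 270)) {
    ar <- (a + c_shift) %% 360
    br <- (b + c_shift) %% 360
    expect_equal(circular_mean(ar), (circular_mean(a) + c_shift) %% 360,
                 tolerance = 1e-9)
    expect_equal(circular_median(ar), (circular_median(a) + c_shift) %% 360,
                 tolerance = 1e-9)
    expect_equal(circular_variance(ar), circular_variance(a),
                 tolerance = 1e-12)
    expect_equal(kuiper_two_sample(ar, br, n_perm = 10, seed = 4)$statistic,
                 kuiper_two_sample(a, b, n_perm = 10, seed = 4)$statistic,
                 tolerance = 1e-12)
    expect_equal(common_median_test(list(ar, br))$statistic,
                 common_median_test(list(a, b))$statistic,
                 tolerance = 1e-9)
  }
})
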