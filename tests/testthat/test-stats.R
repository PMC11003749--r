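test_that("SVD pooling scales to the strongest experiment", {
  tt <- seq(-190, 1000, by = 10)
  base <- outer(exp(-((tt - 150) / 120)^2), c(0.5, 1, 2) / 2)
  one <- svd_pool_scale(list(base), list(c(0.06, 0.12, 0.24)), times = tt)
  expect_equal(one$scale_factors, 1)
  expect_equal(one$weights, 1)

  two <- svd_pool_scale(list(base, 0.5 * base),
                        list(c(0.06, 0.12, 0.24), c(0.06, 0.12, 0.24)),
                        times = tt)
  expect_equal(unname(two$scale_factors), c(1, 2), tolerance = 1e-10)
  expect_equal(unname(two$weights), c(1, 0.25), tolerance = 1e-10)
  expect_equal(two$weights, 1 / two$scale_factors^2)

  expect_error(svd_pool_scale(list(base * 0), list(c(0.06, 0.12, 0.24)),
                              times = tt), "rank 0")
})

test_that("SVD pooling is invariant to per-experiment gain", {
  tt <- seq(-190, 1000, by = 10)
  # shared response structure (rank one across experiments) so the
  # invariance is exact; different contrast grids exercise interpolation
  # contrast response linear through the origin, so interior interpolation
  # preserves the shared rank-one structure
  dyn <- exp(-((tt - 150) / 120)^2)
  resp <- list(outer(dyn, c(0.25, 0.5, 1)),
               outer(dyn, c(0.25, 1)),
               outer(dyn, c(0.25, 0.5, 1)))
  cons <- list(c(0.06, 0.12, 0.24), c(0.06, 0.24), c(0.06, 0.12, 0.24))
  p1 <- svd_pool_scale(resp, cons, times = tt)
  gains <- c(1, 3.7, 0.2)
  p2 <- svd_pool_scale(Map(function(m, g) m * g, resp, gains), cons,
                       times = tt)
  # each experiment's post-scaling contribution (gain x scale) changes only
  # by a factor common to all experiments
  ratio <- (gains * p2$scale_factors) / p1$scale_factors
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-8)
})

test_that("pooled weighted mean/SD implements the printed estimator", {
  x <- c(1, 2, 3, 4)
  expect_equal(weighted_mean_sd(x, 1),
               c(mean = mean(x), sd = stats::sd(x) * sqrt(3 / 4)))
  expect_equal(weighted_mean_sd(5, 0.3), c(mean = 1.5, sd = 0))

  # brute-force oracle on a random weighted mixture
  set.seed(4)
  r <- stats::rnorm(13); w <- stats::runif(13, 0.2, 2)
  got <- weighted_mean_sd(r, w)
  m <- sum(w * r) / 13
  expect_equal(unname(got["mean"]), m, tolerance = 1e-14)
  expect_equal(unname(got["sd"]), sqrt(sum((w * r - m)^2) / 13),
               tolerance = 1e-14)
  expect_error(weighted_mean_sd(numeric(0)), "no values")
})

test_that("z-score normalization pins the in-window residual SD to one", {
  tt <- seq(-200, 990, by = 10)
  set.seed(9)
  sig <- 0.37
  mat <- matrix(0, 60, length(tt))
  cond <- rep(c("a", "b"), each = 30)
  mat[cond == "b", ] <- 2
  mat <- mat + matrix(stats::rnorm(length(mat), sd = sig), nrow(mat))
  z <- zscore_normalize(mat, cond, times = tt)
  keep <- tt >= 50 & tt <= 250
  resid <- z
  for (g in split(seq_len(nrow(z)), cond)) {
    resid[g, ] <- sweep(z[g, ], 2, colMeans(z[g, , drop = FALSE]))
  }
  expect_lt(abs(stats::sd(as.vector(resid[, keep])) - 1), 0.05)

  # scale invariance
  z2 <- zscore_normalize(10 * mat, cond, times = tt)
  expect_equal(as.vector(z2), as.vector(z), tolerance = 1e-12)

  expect_error(zscore_normalize(matrix(1, 4, length(tt)), rep("a", 4),
                                times = tt), "zero residual")
})

test_that("reaction-time censoring keeps exactly the pre-saccade frames", {
  tt <- seq(-90, 200, by = 10)   # frames 10..30 are post-onset
  mk <- function(x) decoded_series(rep(x, length(tt)), tt, "retinotopic")
  # integrate mode
  got <- censor_after_saccade(list(mk(3), mk(5)), c(NA, 95), "integrate")
  expect_equal(got, c(3, 5))
  s <- decoded_series(seq_along(tt), tt, "retinotopic")
  got2 <- censor_after_saccade(list(s), 100, "integrate")
  expect_equal(got2, mean(seq_along(tt)[tt >= 0 & tt <= 100]))

  # framewise: trials with rts 100 and 200, constant values a and b
  fw <- censor_after_saccade(list(mk(2), mk(6)), c(100, 200), "framewise")
  expect_equal(fw$values[tt <= 100], rep(4, sum(tt <= 100)))
  expect_equal(fw$values[tt > 100 & tt <= 200], rep(6, sum(tt > 100 &
                                                             tt <= 200)))
  expect_warning(censor_after_saccade(list(mk(1), mk(2)), c(-50, NA),
                                      "framewise"), "before onset")
})

test_that("weighted correlation reduces to Pearson and flags degeneracies", {
  set.seed(21)
  x <- stats::rnorm(9); y <- stats::rnorm(9)
  wc <- weighted_correlation(x, y, rep(2.5, 9))
  expect_equal(wc$rho, stats::cor(x, y), tolerance = 1e-12)
  expect_equal(wc$n_eff, 9, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(wc$p_value, ct$p.value, tolerance = 1e-10)

  # perfect linear relation
  w <- stats::runif(9, 0.5, 4)
  expect_equal(weighted_correlation(x, 2 * x + 1, w)$rho, 1,
               tolerance = 1e-12)

  # highly concentrated weights: n_eff from the entropy oracle
  wts <- c(0.97, 0.01, 0.01, 0.01) * 400
  p <- wts / sum(wts)
  oracle <- exp(-sum(p * log(p)))
  wc2 <- weighted_correlation(x[1:4], y[1:4], wts)
  expect_equal(wc2$n_eff, oracle, tolerance = 1e-12)
  expect_lt(wc2$n_eff, 1.3)

  # zero variance flags the result undefined
  expect_false(weighted_correlation(rep(1, 5), y[1:5], w[1:5])$defined)
})

test_that("weighted correlation is invariant to affine maps and weight scale", {
  set.seed(33)
  for (k in 1:5) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    w <- stats::runif(8, 0.1, 5)
    r0 <- weighted_correlation(x, y, w)
    r1 <- weighted_correlation(3 * x - 7, -2 * y + 1, w * 11)
    expect_equal(abs(r1$rho), abs(r0$rho), tolerance = 1e-12)
    expect_equal(r1$n_eff, r0$n_eff, tolerance = 1e-12)
  }
})

test_that("effective sample size is maximized at equal weights", {
  set.seed(14)
  n <- 7
  x <- stats::rnorm(n); y <- stats::rnorm(n)
  n_eq <- weighted_correlation(x, y, rep(1, n))$n_eff
  expect_equal(n_eq, n, tolerance = 1e-12)
  for (k in 1:20) {
    w <- stats::runif(n, 0.05, 5)
    expect_lte(weighted_correlation(x, y, w)$n_eff, n_eq + 1e-12)
  }
})

test_that("trend selection: exact cases pick the right model", {
  th <- c(-60, -45, -30, -15, 0, 15, 30, 45, 60, 90)
  lin <- fit_orientation_trend(0.03 * th + 1, th)
  expect_equal(lin$model, "flat")

  g <- 2 * exp(-th^2 / (2 * 30^2)) + 1
  gf <- fit_orientation_trend(g, th)
  expect_equal(gf$model, "gaussian")
  expect_equal(unname(gf$params["A"]), 2, tolerance = 1e-6)
  expect_equal(unname(gf$params["sigma"]), 30, tolerance = 1e-6)
  expect_equal(unname(gf$params["c"]), 1, tolerance = 1e-6)

  expect_error(fit_orientation_trend(1:3, c(0, 15, 30)), ">= 5")
})
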