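test_that("bridge moments match the closed form", {
  # endpoints: only telemetry error remains
  b0 <- bridge_moments(c(1, 2), c(5, 7), 7200, 0, 0.3, 15)
  expect_equal(b0$mean, c(1, 2))
  expect_equal(b0$variance, 225)
  # midpoint with no motion variance: half the error variance
  bm <- bridge_moments(c(0, 0), c(100, 0), 3600, 0.5, 0, 15)
  expect_identical(bm$variance, 15^2 / 2)
  # hand-computed arithmetic case
  bw <- bridge_moments(c(0, 0), c(1000, 0), 7200, 0.5, 0.1, 15)
  expect_equal(bw$mean, c(500, 0))
  expect_equal(bw$variance, 292.5, tolerance = 1e-12)
  # variance is symmetric in alpha <-> 1 - alpha
  a <- seq(0.05, 0.45, by = 0.05)
  v1 <- bridge_moments(c(0, 0), c(1, 1), 100, a, 0.2, 7)$variance
  v2 <- bridge_moments(c(0, 0), c(1, 1), 100, 1 - a, 0.2, 7)$variance
  expect_equal(v1, v2)
  expect_error(bridge_moments(c(0, 0), c(1, 1), -1, 0.5, 0.1, 15),
               "positive")
})

test_that("motion-variance MLE: degenerate and monotone behaviour", {
  fw <- data.frame(t = t_origin + (0:10) * 7200, x = 0, y = 0)
  expect_equal(estimate_bm_variance(fw, 15), 0)
  expect_error(estimate_bm_variance(fw[1:2, ], 15), "3 fixes")
  # a midpoint displaced off the connecting line needs more motion variance
  on_line <- data.frame(t = t_origin + (0:2) * 7200,
                        x = c(0, 500, 1000), y = c(0, 0, 0))
  off_line <- on_line
  off_line$y[2] <- 100
  expect_lte(estimate_bm_variance(on_line, 10),
             estimate_bm_variance(off_line, 10))
  # grid-search oracle for the off-line case
  ll <- function(s2) {
    b <- bridge_moments(c(0, 0), c(1000, 0), 14400, 0.5, s2, 10)
    v <- b$variance + 10^2  # scored fix's own error
    dnorm(500, b$mean[1], sqrt(v), log = TRUE) +
      dnorm(100, b$mean[2], sqrt(v), log = TRUE)
  }
  grid <- 10^seq(-6, 2, length.out = 400)
  s2_grid <- grid[which.max(vapply(grid, ll, numeric(1)))]
  expect_equal(estimate_bm_variance(off_line, 10), s2_grid,
               tolerance = 0.05)
})

test_that("window 11 / margin 5 admits exactly one interior breakpoint", {
  expect_equal(movephase:::break_candidates(11, 5), 6L)  # 0-based index 5
  expect_equal(length(movephase:::break_candidates(13, 5)), 3L)
})

test_that("variance profile is stable on a homogeneous Brownian track", {
  tr <- mk_brownian(600, 0.5, 3, seed = 2)
  vp <- dynamic_variance_profile(tr, dbbmm_config(telemetry_error_sd = 3))
  expect_equal(length(vp$sigma2), n_fixes(tr) - 1L)
  expect_true(all(vp$sigma2 >= 0))
  expect_lt(mean(vp$windows$break_selected), 0.25)
  expect_lt(sd(vp$sigma2) / mean(vp$sigma2), 0.5)
  expect_equal(mean(vp$sigma2), 0.5, tolerance = 0.15)
})

test_that("variance profile tracks a behavioural break", {
  set.seed(11)
  n_half <- 36
  hd <- cumsum(rnorm(n_half, 0, 0.3))
  x <- c(rep(0, n_half), cumsum(400 * cos(hd)))
  y <- c(rep(0, n_half), cumsum(400 * sin(hd)))
  tr <- mk_traj(x + rnorm(2 * n_half, 0, 15), y + rnorm(2 * n_half, 0, 15))
  vp <- dynamic_variance_profile(tr)
  third <- floor((2 * n_half - 1) / 3)
  expect_gt(mean(vp$sigma2[(2 * n_half - third):(2 * n_half - 1)]),
            5 * mean(vp$sigma2[1:third]))
})

test_that("short trajectories fall back to a single static variance", {
  tr <- mk_brownian(8, 0.1, 15, seed = 3)
  expect_message(vp <- dynamic_variance_profile(tr), "static")
  expect_equal(length(unique(vp$sigma2)), 1L)
})

test_that("UD construction: normalisation, ridge, refinement, degenerate", {
  expect_error(compute_ud(mk_traj(c(0, 10), c(0, 0)),
                          list(sigma2 = c(1, 2))), "profile length")
  # two distant fixes: the densest cell sits on the connecting segment
  tr <- mk_traj(c(0, 1000), c(0, 0))
  ud <- compute_ud(tr, list(sigma2 = 0.05), dbbmm_config())
  expect_equal(sum(ud$values), 1, tolerance = 1e-9)
  w <- which(ud$values == max(ud$values), arr.ind = TRUE)
  peak_y <- ud$origin[2] + (w[1] - 0.5) * ud$cell_size
  expect_lt(abs(peak_y - 0), ud$cell_size)
  # halving the cell size barely moves isopleth areas on a smooth fixture
  uda <- compute_ud(tr, list(sigma2 = 0.5), dbbmm_config(cell_size = 20))
  udb <- compute_ud(tr, list(sigma2 = 0.5), dbbmm_config(cell_size = 10))
  aa <- isopleth_area(uda, c(0.5, 0.95))
  ab <- isopleth_area(udb, c(0.5, 0.95))
  expect_lt(max(abs(ab - aa) / aa), 0.05)
  # single fix: minimum 10x10 grid, telemetry-error Gaussian
  ud1 <- compute_ud(mk_traj(0, 0), NULL, dbbmm_config(cell_size = 5))
  expect_gte(nrow(ud1$values), 10L)
  expect_gte(ncol(ud1$values), 10L)
  expect_equal(sum(ud1$values), 1, tolerance = 1e-9)
})

test_that("isopleth areas are monotone and bounded by the support", {
  tr <- mk_brownian(60, 0.1, 15, seed = 4)
  ud <- compute_ud(tr, cfg = dbbmm_config())
  a <- isopleth_area(ud, c(0.2, 0.5, 0.95, 0.999))
  expect_true(all(diff(a) > 0))
  support_ha <- sum(ud$values > 0) * ud$cell_size^2 / 1e4
  expect_lte(a[["99.9%"]], support_ha)
  expect_error(isopleth_area(ud, 1.2), "levels")
})

test_that("KDE home range matches the Gaussian convolution closed form", {
  set.seed(4)
  n <- 500
  tr <- mk_traj(rnorm(n, 0, 500), rnorm(n, 0, 500))
  a <- kde_home_range(tr)
  h <- attr(a, "h")
  expect_equal(h, 500 * n^(-1 / 6), tolerance = 0.1)
  closed <- pi * qchisq(0.95, 2) * (500^2 + h^2) / 1e6
  expect_equal(as.numeric(a), closed, tolerance = 0.2)
  # tight cluster: area dominated by the bandwidth
  set.seed(5)
  tc <- mk_traj(rnorm(40, 0, 1), rnorm(40, 0, 1))
  at <- kde_home_range(tc)
  expect_equal(as.numeric(at),
               pi * qchisq(0.95, 2) * attr(at, "h")^2 / 1e6,
               tolerance = 0.35)
  expect_identical(as.numeric(kde_home_range(tr)), as.numeric(a))
  expect_error(kde_home_range(mk_traj(1:10, 1:10)), "30 fixes")
})

test_that("release-site composition: uniform, half-plane, buffer radius", {
  uni <- release_site_composition(c(3000, 3000), mk_uniform(n = 200))
  expect_equal(unname(uni[["upland_pine"]]), 1)
  expect_equal(sum(uni), 1)
  fr <- release_site_composition(c(3000, 3000), mk_halfplane(), 8.3)
  expect_equal(unname(fr["bottomland"]), 0.5, tolerance = 0.02)
  expect_equal(unname(fr["upland_pine"]), 0.5, tolerance = 0.02)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  # the 8.3 km^2 buffer radius is about 1.6 km
  expect_equal(sqrt(8.3e6 / pi), 1625.414, tolerance = 1e-3)
  expect_error(release_site_composition(c(100, 100), mk_uniform()),
               "exits the raster")
})
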