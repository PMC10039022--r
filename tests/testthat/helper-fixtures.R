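# shared fixture builders (all synthetic, generated in code)

t_origin <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC")

# trajectory from coordinate vectors at a fixed cadence
mk_traj <- function(x, y, dt = 7200, pdop = NA_real_, id = "a1",
                    status = "resident", release_xy = c(x[1], y[1]),
                    capture_xy = NULL, release_habitat = "upland_pine",
                    t = NULL) {
  if (is.null(t)) t <- t_origin + (seq_along(x) - 1) * dt
  trajectory(data.frame(t = t, x = x, y = y, pdop = pdop),
             animal_meta(id, status, release_habitat,
                         release_xy = release_xy, capture_xy = capture_xy))
}

# pure Brownian-motion track observed with telemetry noise
mk_brownian <- function(n, sigma2, delta, dt = 7200, seed = 1) {
  set.seed(seed)
  x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma2 * dt))))
  y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma2 * dt))))
  mk_traj(x + rnorm(n, 0, delta), y + rnorm(n, 0, delta), dt = dt)
}

# two-class vertical half-plane landscape (bottomland left, pine right)
mk_halfplane <- function(n = 200, cell = 30) {
  v <- matrix(0L, n, n)
  v[, 1:(n / 2)] <- 1L
  v[, (n / 2 + 1):n] <- 2L
  landscape_raster(v, c(0, 0), cell)
}

# uniform single-class landscape
mk_uniform <- function(class_code = 2L, n = 100, cell = 30) {
  landscape_raster(matrix(class_code, n, n), c(0, 0), cell)
}

# tiny deterministic choice-set table: n_strata strata of 1 used + n_alt
# alternatives with given covariate generator
mk_toy_strata <- function(n_strata, n_alt, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_strata), function(s) {
    data.frame(stratum_id = s, animal_id = paste0("an", s %% 3),
               used = c(1L, rep(0L, n_alt)),
               x1 = rnorm(n_alt + 1), x2 = rnorm(n_alt + 1))
  }))
}
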