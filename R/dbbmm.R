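#' Dynamic Brownian bridge configuration
#'
#' Defaults follow common practice for 2-h fix schedules: an 11-fix sliding
#' window (22 h) with a 5-fix margin for the motion-variance profile, a 15 m
#' telemetry error SD, and a 30 m grid (NLCD-like resolution).
#'
#' @param window_size Sliding-window length in fixes; odd and > 2 * margin.
#' @param margin Fixes excluded at each window edge when locating
#'   behavioural breaks.
#' @param telemetry_error_sd Telemetry error SD delta, metres.
#' @param cell_size Utilisation-distribution cell edge, metres.
#' @param grid_pad Grid padding as a multiple of the largest positional SD.
#' @param substeps_per_bridge Number of interpolation points used to
#'   integrate each bridge.
#' @return A list of class `dbbmm_config`.
#' @export
dbbmm_config <- function(window_size = 11, margin = 5,
                         telemetry_error_sd = 15, cell_size = 30,
                         grid_pad = 3, substeps_per_bridge = 10) {
  stopifnot(window_size %% 2 == 1, window_size > 2 * margin,
            telemetry_error_sd > 0, cell_size > 0, substeps_per_bridge >= 1)
  structure(list(window_size = as.integer(window_size),
                 margin = as.integer(margin),
                 telemetry_error_sd = telemetry_error_sd,
                 cell_size = cell_size, grid_pad = grid_pad,
                 substeps_per_bridge = as.integer(substeps_per_bridge)),
            class = "dbbmm_config")
}

#' Brownian bridge moments at an interpolation fraction
#'
#' For a bridge between observed endpoints `a` and `b` separated by `T`
#' seconds, the position at fraction `alpha` is bivariate normal with mean
#' `a + alpha (b - a)` and isotropic per-coordinate variance
#' `T alpha (1 - alpha) sigma_m2 + (1 - alpha)^2 delta^2 + alpha^2 delta^2`,
#' where `sigma_m2` is the Brownian motion variance (m^2/s) and `delta` the
#' telemetry error SD (m).
#'
#' @param a,b Numeric length-2 endpoint coordinates, metres.
#' @param T_s Bridge duration, seconds (> 0).
#' @param alpha Interpolation fraction(s) in `[0, 1]`.
#' @param sigma_m2 Brownian motion variance, m^2/s.
#' @param delta Telemetry error SD, metres.
#' @return List with `mean` (length-2, or 2-column matrix for vector
#'   `alpha`) and `variance` (per-coordinate, m^2).
#' @export
bridge_moments <- function(a, b, T_s, alpha, sigma_m2, delta) {
  if (any(T_s <= 0)) stop("bridge duration must be positive", call. = FALSE)
  stopifnot(all(alpha >= 0 & alpha <= 1))
  mx <- a[1] + alpha * (b[1] - a[1])
  my <- a[2] + alpha * (b[2] - a[2])
  v <- T_s * alpha * (1 - alpha) * sigma_m2 +
    (1 - alpha)^2 * delta^2 + alpha^2 * delta^2
  if (length(alpha) == 1) {
    list(mean = c(mx, my), variance = v)
  } else {
    list(mean = cbind(mx, my), variance = v)
  }
}

# log-likelihood of scored fixes under bridges between their neighbours,
# vectorised over the scored set; the scored fix's own telemetry noise
# (+delta^2) adds to the bridge variance, which only propagates the
# endpoints' noise
bm_loglik <- function(fx, fy, ft, scored, sigma_m2, delta) {
  i <- scored
  T_s <- ft[i + 1] - ft[i - 1]
  al <- (ft[i] - ft[i - 1]) / T_s
  v <- T_s * al * (1 - al) * sigma_m2 +
    ((1 - al)^2 + al^2) * delta^2 + delta^2
  mx <- fx[i - 1] + al * (fx[i + 1] - fx[i - 1])
  my <- fy[i - 1] + al * (fy[i + 1] - fy[i - 1])
  sum(stats::dnorm(fx[i], mx, sqrt(v), log = TRUE) +
      stats::dnorm(fy[i], my, sqrt(v), log = TRUE))
}

# MLE of sigma_m2 over a scored set; 1-D bounded search on log sigma_m2
bm_fit <- function(fx, fy, ft, scored, delta) {
  if (length(scored) == 0) return(0)
  dt <- diff(ft)
  upper <- max(1e-6, 10 * max((diff(fx)^2 + diff(fy)^2) / dt, na.rm = TRUE))
  opt <- stats::optimize(function(ls2) {
    -bm_loglik(fx, fy, ft, scored, exp(ls2), delta)
  }, interval = c(log(1e-10), log(upper)), tol = 1e-8)
  s2 <- exp(opt$minimum)
  if (s2 < 2e-10) s2 <- 0  # lower bound: no detectable motion variance
  s2
}

# 1-based indices of the odd interior fixes (classical leave-one-out set)
odd_interior <- function(n) if (n < 3) integer(0) else seq(2L, n - 1L, by = 2L)

#' Maximum-likelihood Brownian motion variance for a window of fixes
#'
#' Leave-one-out estimator: the likelihood is the product, over the odd
#' interior fixes, of the bivariate normal density of each such fix under
#' the Brownian bridge between its temporal neighbours ([bridge_moments()]
#' at its interpolation fraction). Maximised by bounded 1-D search on
#' log sigma_m2 with lower bound 0.
#'
#' @param fix_window Data frame with columns `t`, `x`, `y` (>= 3 rows).
#' @param delta Telemetry error SD, metres.
#' @return Estimated Brownian motion variance, m^2/s.
#' @export
estimate_bm_variance <- function(fix_window, delta) {
  n <- nrow(fix_window)
  if (n < 3) stop("need at least 3 fixes to estimate sigma_m2", call. = FALSE)
  bm_fit(fix_window$x, fix_window$y, as.numeric(fix_window$t),
         odd_interior(n), delta)
}

# candidate breakpoints (1-based local index) at least `margin` fixes from
# both window edges
break_candidates <- function(window_size, margin) {
  lo <- margin + 1L
  hi <- window_size - margin
  if (lo > hi) integer(0) else seq.int(lo, hi)
}

#' Sliding-window dynamic Brownian motion variance profile
#'
#' Moves a window of `window_size` fixes along the path. In each window a
#' single-variance model is compared (by BIC, 1 vs 2 variance parameters)
#' against models with one variance change at each candidate breakpoint
#' located at least `margin` fixes from both window edges. Scoring uses the
#' odd interior fixes of each candidate's two parts for both models, so the
#' two log-likelihoods are comparable. The selected model's variances are
#' assigned to the steps adjacent to the window's core fix, and each step's
#' final sigma_m2 is the mean over all windows covering it; uncovered edge
#' steps inherit the nearest covered value.
#'
#' @param traj A [trajectory()].
#' @param cfg A [dbbmm_config()].
#' @return Object of class `variance_profile`: list with `sigma2` (m^2/s,
#'   one per step) and `windows` (per-window bookkeeping, including whether
#'   a break was selected).
#' @export
dynamic_variance_profile <- function(traj, cfg = dbbmm_config()) {
  f <- traj$fixes
  n <- nrow(f)
  if (n < 2) stop("need at least 2 fixes", call. = FALSE)
  delta <- cfg$telemetry_error_sd
  fx <- f$x; fy <- f$y; ft <- as.numeric(f$t)
  n_steps <- n - 1L
  if (n < cfg$window_size) {
    message("trajectory shorter than the sliding window; using a single ",
            "static sigma_m2")
    s2 <- bm_fit(fx, fy, ft, odd_interior(n), delta)
    return(structure(list(sigma2 = rep(s2, n_steps),
                          windows = data.frame(start = integer(0),
                                               break_selected = logical(0))),
                     class = "variance_profile"))
  }
  ws <- cfg$window_size
  mg <- cfg$margin
  cand <- break_candidates(ws, mg)
  acc <- numeric(n_steps)
  cnt <- integer(n_steps)
  n_win <- n - ws + 1L
  win_break <- logical(n_win)
  win_sigma <- numeric(n_win)
  for (w in seq_len(n_win)) {
    idx <- w:(w + ws - 1L)
    wx <- fx[idx]; wy <- fy[idx]; wt <- ft[idx]
    best <- NULL
    for (j in cand) {
      sc_l <- odd_interior(j)                       # left part: fixes 1..j
      sc_r <- j - 1L + odd_interior(ws - j + 1L)    # right part: fixes j..ws
      sc <- c(sc_l, sc_r)
      s_one <- bm_fit(wx, wy, wt, sc, delta)
      ll_one <- bm_loglik(wx, wy, wt, sc, s_one, delta)
      s_l <- bm_fit(wx, wy, wt, sc_l, delta)
      s_r <- bm_fit(wx, wy, wt, sc_r, delta)
      ll_two <- bm_loglik(wx, wy, wt, sc_l, s_l, delta) +
        bm_loglik(wx, wy, wt, sc_r, s_r, delta)
      m <- length(sc)
      bic_one <- -2 * ll_one + log(m)
      bic_two <- -2 * ll_two + 2 * log(m)
      rec <- list(j = j, s_one = s_one, s_l = s_l, s_r = s_r,
                  bic_one = bic_one, bic_two = bic_two)
      if (is.null(best) || bic_two < best$bic_two) best <- rec
    }
    use_break <- best$bic_two < best$bic_one
    win_break[w] <- use_break
    core <- w + mg  # global index of the window's core fix
    if (!use_break) {
      # final no-break estimate uses every leave-one-out point of the window
      best$s_one <- bm_fit(wx, wy, wt, odd_interior(ws), delta)
    }
    if (use_break) {
      b <- w + best$j - 1L
      if (b - 1L >= 1L) { acc[b - 1L] <- acc[b - 1L] + best$s_l
                          cnt[b - 1L] <- cnt[b - 1L] + 1L }
      if (b <= n_steps) { acc[b] <- acc[b] + best$s_r
                          cnt[b] <- cnt[b] + 1L }
      win_sigma[w] <- (best$s_l + best$s_r) / 2
    } else {
      for (s in c(core - 1L, core)) {
        if (s >= 1L && s <= n_steps) { acc[s] <- acc[s] + best$s_one
                                       cnt[s] <- cnt[s] + 1L }
      }
      win_sigma[w] <- best$s_one
    }
  }
  sigma2 <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  covered <- which(cnt > 0)
  if (length(covered) == 0) stop("no step covered by any window core",
                                 call. = FALSE)
  for (s in which(cnt == 0)) {
    sigma2[s] <- sigma2[covered[which.min(abs(covered - s))]]
  }
  structure(list(sigma2 = sigma2,
                 windows = data.frame(start = seq_len(n_win),
                                      break_selected = win_break,
                                      sigma2 = win_sigma)),
            class = "variance_profile")
}

#' Utilisation-distribution grid
#'
#' Raster of occupancy probability mass; same bottom-first matrix layout as
#' [landscape_raster()]. Mass sums to 1.
#' @param values Numeric matrix of non-negative masses.
#' @param origin Lower-left corner, metres.
#' @param cell_size Cell edge, metres.
#' @return Object of class `ud_grid`.
#' @export
ud_grid <- function(values, origin, cell_size) {
  stopifnot(is.matrix(values), all(values >= 0), cell_size > 0)
  structure(list(values = values / sum(values), origin = as.numeric(origin),
                 cell_size = cell_size), class = "ud_grid")
}

#' Brownian bridge utilisation distribution of a trajectory
#'
#' Integrates, for every step, the bivariate normal of [bridge_moments()]
#' over `substeps_per_bridge` equally spaced interpolation fractions,
#' weighting each bridge by its duration; cell mass is the density at the
#' cell centre times cell area, and the grid is normalised to total mass 1.
#' Zero-displacement bridges use the full telemetry-error variance delta^2
#' at every fraction, so a motionless animal's UD is exactly the
#' telemetry-error Gaussian.
#'
#' @param traj A [trajectory()] (a single fix yields the telemetry-error
#'   Gaussian around that point).
#' @param profile A [dynamic_variance_profile()] for `traj`, or `NULL` to
#'   compute one.
#' @param cfg A [dbbmm_config()].
#' @return A [ud_grid()].
#' @export
compute_ud <- function(traj, profile = NULL, cfg = dbbmm_config()) {
  f <- traj$fixes
  n <- nrow(f)
  delta <- cfg$telemetry_error_sd
  cs <- cfg$cell_size
  K <- cfg$substeps_per_bridge
  if (n == 0) stop("empty trajectory", call. = FALSE)
  if (n == 1) {
    mx <- f$x; my <- f$y; sds <- delta; wts <- 1
  } else {
    if (is.null(profile)) profile <- dynamic_variance_profile(traj, cfg)
    s2 <- profile$sigma2
    if (length(s2) != n - 1) {
      stop("variance profile length must equal the step count", call. = FALSE)
    }
    al <- (seq_len(K) - 0.5) / K
    x0 <- rep(f$x[-n], each = K); y0 <- rep(f$y[-n], each = K)
    x1 <- rep(f$x[-1], each = K); y1 <- rep(f$y[-1], each = K)
    T_s <- rep(diff(as.numeric(f$t)), each = K)
    s2e <- rep(s2, each = K)
    alv <- rep(al, n - 1)
    mx <- x0 + alv * (x1 - x0)
    my <- y0 + alv * (y1 - y0)
    v <- T_s * alv * (1 - alv) * s2e + ((1 - alv)^2 + alv^2) * delta^2
    zero_disp <- (x0 == x1 & y0 == y1)
    v[zero_disp] <- delta^2
    sds <- sqrt(v)
    wts <- T_s / K
  }
  pad <- cfg$grid_pad * max(sds)
  gx0 <- floor((min(f$x) - pad) / cs) * cs
  gy0 <- floor((min(f$y) - pad) / cs) * cs
  nc <- ceiling((max(f$x) + pad - gx0) / cs)
  nr <- ceiling((max(f$y) + pad - gy0) / cs)
  if (nc < 10) { gx0 <- gx0 - ceiling((10 - nc) / 2) * cs; nc <- 10L }
  if (nr < 10) { gy0 <- gy0 - ceiling((10 - nr) / 2) * cs; nr <- 10L }
  xc <- gx0 + (seq_len(nc) - 0.5) * cs
  yc <- gy0 + (seq_len(nr) - 0.5) * cs
  M <- matrix(0, nr, nc)
  for (k in seq_along(mx)) {
    s5 <- 5 * sds[k]
    j1 <- max(1L, floor((mx[k] - s5 - gx0) / cs) + 1L)
    j2 <- min(nc, floor((mx[k] + s5 - gx0) / cs) + 1L)
    i1 <- max(1L, floor((my[k] - s5 - gy0) / cs) + 1L)
    i2 <- min(nr, floor((my[k] + s5 - gy0) / cs) + 1L)
    if (j1 > j2 || i1 > i2) next
    dx <- stats::dnorm(xc[j1:j2], mx[k], sds[k])
    dy <- stats::dnorm(yc[i1:i2], my[k], sds[k])
    M[i1:i2, j1:j2] <- M[i1:i2, j1:j2] + wts[k] * outer(dy, dx)
  }
  ud_grid(M, c(gx0, gy0), cs)
}

#' Isopleth areas of a utilisation distribution
#'
#' The level-p isopleth is the smallest set of cells whose cumulative mass
#' reaches p, taking cells in decreasing order of mass (ties broken by
#' row-major cell index, deterministically).
#'
#' @param ud A [ud_grid()].
#' @param levels Probabilities in (0, 1); defaults to the 50% core area and
#'   95% range area.
#' @return Named numeric vector of areas in hectares.
#' @export
isopleth_area <- function(ud, levels = c(0.5, 0.95)) {
  if (any(levels <= 0 | levels >= 1)) {
    stop("isopleth levels must lie in (0, 1)", call. = FALSE)
  }
  v <- as.vector(ud$values)  # column-major
  nr <- nrow(ud$values)
  col_idx <- (seq_along(v) - 1L) %/% nr + 1L
  row_idx <- (seq_along(v) - 1L) %% nr + 1L
  rm_idx <- (row_idx - 1L) * ncol(ud$values) + col_idx
  ord <- order(-v, rm_idx)
  cum <- cumsum(v[ord])
  out <- vapply(levels, function(p) {
    k <- which(cum >= p - 1e-12)[1]
    if (is.na(k)) k <- length(v)
    k * ud$cell_size^2 / 1e4
  }, numeric(1))
  names(out) <- paste0(format(100 * levels, trim = TRUE), "%")
  out
}

#' Kernel density home-range area
#'
#' Bivariate normal kernel density estimate with the reference bandwidth
#' `h = sigma_hat * n^(-1/6)`, `sigma_hat = sqrt((var_x + var_y) / 2)`,
#' evaluated on a grid; the home range is the isopleth area at `level`.
#'
#' @param traj A [trajectory()] with at least 30 fixes.
#' @param level Isopleth probability (default 0.95).
#' @param cell_size Grid cell edge in metres; defaults to `h / 4`.
#' @return Area in km^2, with the bandwidth attached as attribute `h`.
#' @export
kde_home_range <- function(traj, level = 0.95, cell_size = NULL) {
  f <- traj$fixes
  n <- nrow(f)
  if (n < 30) stop("need at least 30 fixes for a KDE home range",
                   call. = FALSE)
  sigma_hat <- sqrt((stats::var(f$x) + stats::var(f$y)) / 2)
  if (sigma_hat == 0) sigma_hat <- 1
  h <- sigma_hat * n^(-1 / 6)
  if (is.null(cell_size)) cell_size <- h / 4
  pad <- 4 * h
  gx0 <- min(f$x) - pad; gy0 <- min(f$y) - pad
  nc <- ceiling((max(f$x) + pad - gx0) / cell_size)
  nr <- ceiling((max(f$y) + pad - gy0) / cell_size)
  xc <- gx0 + (seq_len(nc) - 0.5) * cell_size
  yc <- gy0 + (seq_len(nr) - 0.5) * cell_size
  M <- matrix(0, nr, nc)
  for (k in seq_len(n)) {
    s5 <- 5 * h
    j1 <- max(1L, floor((f$x[k] - s5 - gx0) / cell_size) + 1L)
    j2 <- min(nc, floor((f$x[k] + s5 - gx0) / cell_size) + 1L)
    i1 <- max(1L, floor((f$y[k] - s5 - gy0) / cell_size) + 1L)
    i2 <- min(nr, floor((f$y[k] + s5 - gy0) / cell_size) + 1L)
    dx <- stats::dnorm(xc[j1:j2], f$x[k], h)
    dy <- stats::dnorm(yc[i1:i2], f$y[k], h)
    M[i1:i2, j1:j2] <- M[i1:i2, j1:j2] + outer(dy, dx)
  }
  ud <- ud_grid(M, c(gx0, gy0), cell_size)
  area_km2 <- unname(isopleth_area(ud, level)) / 100  # ha -> km^2
  attr(area_km2, "h") <- h
  area_km2
}

#' Write a utilisation distribution as an ESRI ASCII grid
#' @param ud A [ud_grid()].
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ud_ascii <- function(ud, path) {
  v <- ud$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.6f", ud$origin[1]),
               sprintf("yllcorner %.6f", ud$origin[2]),
               sprintf("cellsize %.6f", ud$cell_size),
               "NODATA_value -9999"), con)
  for (i in rev(seq_len(nrow(v)))) {
    writeLines(paste(formatC(v[i, ], format = "e", digits = 8),
                     collapse = " "), con)
  }
  invisible(path)
}
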