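#' Simulation configuration
#'
#' Generative ground truth for end-to-end testing. Defaults emulate the
#' study cohort this package was designed around: 14 residents (4 in upland
#' pine, 10 in bottomland) and 14 translocated animals (8 to upland pine,
#' 6 to bottomland), 90 days of 2-h fixes, 15 m telemetry error, a
#' programmed exploration-to-exploitation switch on day 25, and roughly one
#' in five translocated animals homing back to its capture range within 10
#' days. Selection strength for bottomland is positive (it is the
#' high-quality habitat) and stronger once animals settle.
#'
#' @param n_resident_upland,n_resident_bottomland Resident counts by home
#'   habitat.
#' @param n_translocated_upland,n_translocated_bottomland Translocated
#'   counts by release habitat.
#' @param horizon_days Monitoring horizon (days).
#' @param fix_interval_s Fix cadence, seconds.
#' @param telemetry_error_sd Isotropic telemetry noise SD, metres.
#' @param switch_day First exploitation day for translocated agents (T*).
#' @param homecoming_prob Probability a translocated agent walks home
#'   instead of dispersing.
#' @param beta Named list with elements `exploration` and `exploitation`,
#'   each a named vector of selection strengths for `bottomland` and
#'   `grassland` relative to upland pine.
#' @param beta_status_offset,beta_release_offset Additive shifts applied to
#'   the habitat strengths for translocated animals and for animals
#'   released in bottomland, respectively (named vectors; zero by default).
#'   Non-zero values generate data under the status + release-habitat
#'   model.
#' @param beta_bottomland_weekly Optional numeric vector of week-specific
#'   bottomland strengths overriding `beta` (used to program temporal
#'   trends in selection).
#' @param step_shape,step_scale_explore,step_scale_exploit Gamma step-length
#'   kernel parameters by phase, metres.
#' @param angle_sd_explore,angle_sd_exploit Turning-angle SD (radians,
#'   wrapped normal); small values give directional persistence.
#' @param attraction_resident,attraction_settled,attraction_homing
#'   Range-centre attraction strengths (penalty per km of distance from the
#'   centre) for residents, settled translocated agents (slightly tighter
#'   than residents, as newly settled animals use smaller areas), and
#'   homing walks.
#' @param n_candidates Candidate steps per move in the discrete-choice walk
#'   (simulator internal, independent of the analysis-side random steps).
#' @param min_translocation_m Minimum capture-to-release distance.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_resident_upland = 4, n_resident_bottomland = 10,
                       n_translocated_upland = 8,
                       n_translocated_bottomland = 6,
                       horizon_days = 90, fix_interval_s = 7200,
                       telemetry_error_sd = 15, switch_day = 25,
                       homecoming_prob = 0.2,
                       beta = list(
                         exploration = c(bottomland = 0.3, grassland = -0.2),
                         exploitation = c(bottomland = 1.0, grassland = -0.5)),
                       beta_status_offset = c(bottomland = 0, grassland = 0),
                       beta_release_offset = c(bottomland = 0, grassland = 0),
                       beta_bottomland_weekly = NULL,
                       step_shape = 2,
                       step_scale_explore = 125, step_scale_exploit = 75,
                       angle_sd_explore = 0.4, angle_sd_exploit = 1.8,
                       attraction_resident = 1.1, attraction_settled = 1.8,
                       attraction_homing = 6, n_candidates = 200,
                       min_translocation_m = 10000) {
  stopifnot(horizon_days >= 1, fix_interval_s > 0, telemetry_error_sd > 0,
            homecoming_prob >= 0, homecoming_prob <= 1,
            step_scale_explore > 0, step_scale_exploit > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a patchy synthetic landscape
#'
#' Thresholds a smooth Gaussian random field (white noise convolved with a
#' Gaussian kernel of scale `patch_scale`) at the class-fraction quantiles,
#' which yields contiguous patches whose realised class fractions match the
#' targets almost exactly. Default fractions follow the composition of a
#' bottomland release area (26% bottomland, 44% upland pine).
#'
#' @param seed Integer seed.
#' @param width_m,height_m Landscape extent, metres.
#' @param cell_size Cell edge, metres (NLCD-like 30 m default).
#' @param patch_scale Gaussian correlation scale of the patches, metres;
#'   must be at least 2 cells.
#' @param class_fractions Named fractions over
#'   `bottomland`, `upland_pine`, `grassland`, `excluded`; may sum to less
#'   than 1, in which case the remainder goes to grassland.
#' @param origin Lower-left corner coordinates.
#' @return A [landscape_raster()].
#' @export
generate_landscape <- function(seed, width_m = 24000, height_m = 24000,
                               cell_size = 30, patch_scale = 600,
                               class_fractions = c(bottomland = 0.26,
                                                   upland_pine = 0.44,
                                                   grassland = 0.27,
                                                   excluded = 0.03),
                               origin = c(0, 0)) {
  if (patch_scale < 2 * cell_size) {
    stop("patch_scale below 2 cells produces speckle, not patches",
         call. = FALSE)
  }
  fr <- class_fractions[class_fractions > 0]
  if (sum(fr) > 1 + 1e-9) stop("class fractions must sum to <= 1",
                               call. = FALSE)
  if (sum(fr) < 1 - 1e-9) {
    fr[["grassland"]] <- (if ("grassland" %in% names(fr)) fr[["grassland"]]
                          else 0) + 1 - sum(fr)
  }
  nc <- as.integer(round(width_m / cell_size))
  nr <- as.integer(round(height_m / cell_size))
  set.seed(seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (length(fr) > 1) {
    sd_c <- patch_scale / cell_size
    dx <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
    dy <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
    k <- outer(stats::dnorm(dy, 0, sd_c), stats::dnorm(dx, 0, sd_c))
    z <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
      length(z)
    qs <- stats::quantile(z, cumsum(fr) / sum(fr), names = FALSE)
    cls <- matrix(cut(z, breaks = c(-Inf, qs[-length(qs)], Inf),
                      labels = FALSE), nr, nc)
  } else {
    cls <- matrix(1L, nr, nc)
  }
  legend <- c(excluded = 0L, bottomland = 1L, upland_pine = 2L,
              grassland = 3L)
  codes <- matrix(legend[names(fr)][cls], nr, nc)
  landscape_raster(codes, origin = origin, cell_size = cell_size,
                   legend = legend)
}

# random cell centre of a given class, at least margin_m from the edges
sample_start <- function(landscape, class, margin_m = 2000) {
  v <- landscape$values
  s <- landscape$cell_size
  code <- landscape$legend[[class]]
  jm <- ceiling(margin_m / s)
  ii <- (jm + 1):(nrow(v) - jm)
  jj <- (jm + 1):(ncol(v) - jm)
  sub <- which(v[ii, jj] == code, arr.ind = TRUE)
  if (nrow(sub) == 0) stop("no ", class, " cell available for a start point",
                           call. = FALSE)
  p <- sub[sample.int(nrow(sub), 1), ]
  c(landscape$origin[1] + (jj[p[2]] - 0.5) * s,
    landscape$origin[2] + (ii[p[1]] - 0.5) * s)
}

#' Simulate one agent's trajectory
#'
#' Discrete-choice correlated random walk at the fix cadence: at each move,
#' `n_candidates` candidate steps are drawn from the phase-specific
#' step-length and turning-angle kernels and one is chosen with probability
#' proportional to `exp(beta_class + attraction term)`. Exploration uses
#' long steps with strong directional persistence and no attraction;
#' exploitation uses short, weakly persistent steps with attraction to the
#' range centre (set at settlement). Residents start settled at their
#' capture site; translocated agents switch on `switch_day`; homing agents
#' walk toward their capture site and settle there. Candidates landing on
#' excluded cells or off the raster cannot be chosen. Observed fixes are
#' the true positions plus isotropic Gaussian telemetry noise.
#'
#' @param landscape A [landscape_raster()].
#' @param cfg A [sim_config()].
#' @param role `"resident"`, `"translocated"` or `"homecomer"`.
#' @param start_xy Release position (true), metres; must be on a
#'   non-excluded cell.
#' @param capture_xy Capture position (homing target); defaults to
#'   `start_xy`.
#' @param animal_id Identifier.
#' @param seed Integer seed.
#' @param release_t POSIXct release time.
#' @param release_habitat Habitat class of the release site (drives the
#'   group-offset betas).
#' @return A [trajectory()] with true positions attached as attribute
#'   `true_xy`.
#' @export
simulate_agent <- function(landscape, cfg = sim_config(),
                           role = c("resident", "translocated", "homecomer"),
                           start_xy, capture_xy = NULL, animal_id = "A1",
                           seed = 1,
                           release_t = as.POSIXct("2015-01-01",
                                                  tz = "UTC"),
                           release_habitat = "upland_pine") {
  role <- match.arg(role)
  if (is.null(capture_xy)) capture_xy <- start_xy
  if (class_at(landscape, start_xy[1], start_xy[2]) %in%
      c(NA_character_, "excluded")) {
    stop("start position lies on an excluded cell", call. = FALSE)
  }
  set.seed(seed)
  n_per_day <- as.integer(round(86400 / cfg$fix_interval_s))
  n_fix <- cfg$horizon_days * n_per_day
  tt <- release_t + (seq_len(n_fix) - 1) * cfg$fix_interval_s
  day <- ((seq_len(n_fix) - 1) %/% n_per_day) + 1L
  xs <- ys <- numeric(n_fix)
  xs[1] <- start_xy[1]; ys[1] <- start_xy[2]
  heading <- stats::runif(1, -pi, pi)
  status_translocated <- role != "resident"
  rh_bottom <- release_habitat == "bottomland"
  settled <- role == "resident"
  centre <- if (role == "resident") start_xy else c(NA_real_, NA_real_)
  homing_done <- FALSE
  K <- cfg$n_candidates
  for (i in 2:n_fix) {
    if (role == "translocated" && !settled && day[i] >= cfg$switch_day) {
      settled <- TRUE
      centre <- c(xs[i - 1], ys[i - 1])
    }
    if (role == "homecomer" && !homing_done) {
      if (sqrt((xs[i - 1] - capture_xy[1])^2 +
               (ys[i - 1] - capture_xy[2])^2) <= 1600) {
        homing_done <- TRUE
        settled <- TRUE
        centre <- capture_xy
      }
    }
    exploring <- !settled
    if (exploring) {
      len <- stats::rgamma(K, cfg$step_shape,
                           scale = cfg$step_scale_explore)
      ang <- stats::rnorm(K, 0, cfg$angle_sd_explore)
      b <- cfg$beta$exploration
      att <- if (role == "homecomer") cfg$attraction_homing else 0
      att_centre <- capture_xy
    } else {
      len <- stats::rgamma(K, cfg$step_shape,
                           scale = cfg$step_scale_exploit)
      ang <- stats::rnorm(K, 0, cfg$angle_sd_exploit)
      b <- cfg$beta$exploitation
      att <- if (role == "resident") cfg$attraction_resident else
        cfg$attraction_settled
      att_centre <- centre
    }
    if (status_translocated) b <- b + cfg$beta_status_offset[names(b)]
    if (rh_bottom) b <- b + cfg$beta_release_offset[names(b)]
    if (!is.null(cfg$beta_bottomland_weekly)) {
      w <- min((day[i] - 1L) %/% 7L + 1L, length(cfg$beta_bottomland_weekly))
      b[["bottomland"]] <- cfg$beta_bottomland_weekly[w]
    }
    hd <- wrap_angle(heading + ang)
    cx <- xs[i - 1] + len * cos(hd)
    cy <- ys[i - 1] + len * sin(hd)
    cls <- class_at(landscape, cx, cy)
    score <- rep(-Inf, K)
    ok <- !is.na(cls) & cls != "excluded"
    bval <- c(bottomland = unname(b[["bottomland"]]),
              upland_pine = 0,
              grassland = unname(b[["grassland"]]))
    score[ok] <- bval[cls[ok]]
    if (att > 0) {
      d_km <- sqrt((cx - att_centre[1])^2 + (cy - att_centre[2])^2) / 1000
      score <- score - att * d_km
    }
    if (all(!is.finite(score))) {  # cornered: stay put
      xs[i] <- xs[i - 1]; ys[i] <- ys[i - 1]
      next
    }
    p <- exp(score - max(score[is.finite(score)]))
    p[!is.finite(p)] <- 0
    pick <- sample.int(K, 1, prob = p)
    xs[i] <- cx[pick]; ys[i] <- cy[pick]; heading <- hd[pick]
  }
  obs_x <- xs + stats::rnorm(n_fix, 0, cfg$telemetry_error_sd)
  obs_y <- ys + stats::rnorm(n_fix, 0, cfg$telemetry_error_sd)
  pdop <- round(stats::rlnorm(n_fix, log(2.2), 0.7), 1)
  status <- if (role == "resident") "resident" else "translocated"
  meta <- animal_meta(animal_id, status, release_habitat,
                      release_xy = start_xy, capture_xy = capture_xy)
  tr <- trajectory(data.frame(t = tt, x = obs_x, y = obs_y, pdop = pdop),
                   meta)
  attr(tr, "true_xy") <- cbind(xs, ys)
  tr
}

#' Simulate a full cohort with ground truth
#'
#' Generates a landscape and a cohort of resident and translocated agents
#' (the study-design defaults are 4 + 10 residents and 8 + 6 translocated
#' by habitat), with a `homecoming_prob` fraction of translocated agents
#' walking home within the homing window. Returns everything the analysis
#' pipeline consumes plus the generative truth for recovery scoring.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer master seed (per-animal streams are derived from it).
#' @param landscape Optional pre-built [landscape_raster()].
#' @return List of class `sim_cohort`: `trajectories` (named list),
#'   `meta` (data frame), `landscape`, `truth` (list), `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1, landscape = NULL) {
  if (is.null(landscape)) {
    landscape <- generate_landscape(child_seed(seed, "landscape"))
  }
  release_t <- as.POSIXct("2015-01-01", tz = "UTC")
  plan <- rbind(
    data.frame(role = "resident", habitat = "upland_pine",
               n = cfg$n_resident_upland),
    data.frame(role = "resident", habitat = "bottomland",
               n = cfg$n_resident_bottomland),
    data.frame(role = "translocated", habitat = "upland_pine",
               n = cfg$n_translocated_upland),
    data.frame(role = "translocated", habitat = "bottomland",
               n = cfg$n_translocated_bottomland))
  trajs <- list()
  meta_rows <- list()
  truth_roles <- character(0)
  idx <- 0
  for (r in seq_len(nrow(plan))) {
    if (plan$n[r] == 0) next
    for (k in seq_len(plan$n[r])) {
      idx <- idx + 1
      id <- sprintf("%s_%s_%02d",
                    if (plan$role[r] == "resident") "res" else "tra",
                    if (plan$habitat[r] == "upland_pine") "up" else "bl", k)
      sd_a <- child_seed(seed, paste0("agent_", id))
      set.seed(sd_a)
      if (plan$role[r] == "resident") {
        start <- sample_start(landscape, plan$habitat[r])
        role <- "resident"
        capture <- start
      } else {
        home_hab <- if (plan$habitat[r] == "upland_pine") "bottomland" else
          "upland_pine"
        repeat {
          capture <- sample_start(landscape, home_hab)
          start <- sample_start(landscape, plan$habitat[r])
          if (sqrt(sum((capture - start)^2)) >= cfg$min_translocation_m)
            break
        }
        role <- if (stats::runif(1) < cfg$homecoming_prob) "homecomer" else
          "translocated"
      }
      truth_roles[id] <- role
      trajs[[id]] <- simulate_agent(landscape, cfg, role, start, capture, id,
                                    seed = child_seed(seed,
                                                      paste0("walk_", id)),
                                    release_t = release_t,
                                    release_habitat = plan$habitat[r])
      home_hab <- if (plan$role[r] == "resident") plan$habitat[r] else
        if (plan$habitat[r] == "upland_pine") "bottomland" else "upland_pine"
      meta_rows[[id]] <- data.frame(
        animal_id = id,
        status = if (plan$role[r] == "resident") "resident" else
          "translocated",
        release_habitat = plan$habitat[r], capture_habitat = home_hab,
        release_x = start[1], release_y = start[2],
        capture_x = capture[1], capture_y = capture[2],
        stringsAsFactors = FALSE)
    }
  }
  truth <- list(beta = cfg$beta,
                beta_status_offset = as.list(cfg$beta_status_offset),
                beta_release_offset = as.list(cfg$beta_release_offset),
                beta_bottomland_weekly = cfg$beta_bottomland_weekly,
                switch_day = cfg$switch_day,
                homecomers = names(truth_roles)[truth_roles == "homecomer"])
  structure(list(trajectories = trajs,
                 meta = do.call(rbind, meta_rows),
                 landscape = landscape, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' Write a simulated cohort in the pipeline's input formats
#'
#' Emits `gps.csv`, `meta.csv`, `landcover.asc` and `truth.json` under
#' `dir`; these are exactly the files [run_pipeline()] reads.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gps <- do.call(rbind, lapply(cohort$trajectories, function(tr) {
    data.frame(animal_id = tr$meta$animal_id,
               timestamp = format(tr$fixes$t, "%Y-%m-%dT%H:%M:%S",
                                  tz = "UTC"),
               x = round(tr$fixes$x, 2), y = round(tr$fixes$y, 2),
               pdop = tr$fixes$pdop, stringsAsFactors = FALSE)
  }))
  utils::write.csv(gps, file.path(dir, "gps.csv"), row.names = FALSE)
  utils::write.csv(cohort$meta, file.path(dir, "meta.csv"),
                   row.names = FALSE)
  write_esri_ascii(cohort$landscape, file.path(dir, "landcover.asc"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
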