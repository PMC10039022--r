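#' Animal metadata record
#'
#' Describes one collared animal: its status (resident or translocated),
#' release habitat class, release and capture coordinates (projected metres),
#' and any censoring windows supplied by the analyst (e.g. an animal that
#' began travelling with another collared animal).
#'
#' Residents are released at their capture site, so `release_xy` must equal
#' `capture_xy` for them.
#'
#' @param animal_id Character scalar.
#' @param status `"resident"` or `"translocated"`.
#' @param release_habitat Habitat class at the release site, typically
#'   `"bottomland"` or `"upland_pine"`.
#' @param release_xy,capture_xy Numeric length-2 vectors, projected metres.
#' @param capture_habitat Habitat class of the original capture range
#'   (used to regroup an animal that homes back); `NA` if unknown.
#' @param censor_windows A data frame with POSIXct columns `start`, `end`
#'   giving non-overlapping intervals to drop, or `NULL`.
#' @return An object of class `animal_meta` (a list).
#' @export
animal_meta <- function(animal_id, status = c("resident", "translocated"),
                        release_habitat = NA_character_,
                        release_xy = c(NA_real_, NA_real_),
                        capture_xy = NULL,
                        capture_habitat = NA_character_,
                        censor_windows = NULL) {
  status <- match.arg(status)
  if (is.null(capture_xy)) capture_xy <- release_xy
  release_xy <- as.numeric(release_xy)
  capture_xy <- as.numeric(capture_xy)
  if (status == "resident" && all(is.finite(release_xy)) &&
      !isTRUE(all.equal(release_xy, capture_xy))) {
    stop("resident animals must have release_xy == capture_xy", call. = FALSE)
  }
  if (!is.null(censor_windows)) {
    stopifnot(is.data.frame(censor_windows),
              all(c("start", "end") %in% names(censor_windows)))
    cw <- censor_windows[order(censor_windows$start), , drop = FALSE]
    if (nrow(cw) > 1 &&
        any(as.numeric(cw$start[-1]) < as.numeric(cw$end[-nrow(cw)]))) {
      stop("censor_windows must be non-overlapping", call. = FALSE)
    }
    censor_windows <- cw
  }
  structure(list(animal_id = as.character(animal_id), status = status,
                 release_habitat = release_habitat,
                 release_xy = release_xy, capture_xy = capture_xy,
                 capture_habitat = capture_habitat,
                 censor_windows = censor_windows),
            class = "animal_meta")
}

#' Preprocessing configuration
#'
#' @param target_interval_s Target fix interval in seconds (default 2 h).
#' @param interval_tolerance_s Acceptance half-window around the target
#'   interval, seconds (default 15 min).
#' @param pdop_max Fixes with PDOP strictly greater than this are removed.
#' @param truncate_days Monitoring horizon; fixes after this many days from
#'   the (possibly re-based) first fix are dropped.
#' @param homing_radius_m Radius around the capture site within which a
#'   translocated animal counts as having returned home.
#' @param homing_window_days Returns are only recognised within this many
#'   days of release.
#' @param tz Time zone used to define calendar-day boundaries.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_interval_s = 7200,
                              interval_tolerance_s = 900,
                              pdop_max = 9,
                              truncate_days = 90,
                              homing_radius_m = 1600,
                              homing_window_days = 10,
                              tz = "UTC") {
  stopifnot(target_interval_s > 0, pdop_max > 0, truncate_days > 0)
  structure(list(target_interval_s = target_interval_s,
                 interval_tolerance_s = interval_tolerance_s,
                 pdop_max = pdop_max, truncate_days = truncate_days,
                 homing_radius_m = homing_radius_m,
                 homing_window_days = homing_window_days, tz = tz),
            class = "preprocess_config")
}

#' Construct a trajectory
#'
#' A trajectory is one animal's time-ordered sequence of GPS fixes plus its
#' metadata. Fixes are sorted by timestamp on construction; duplicate
#' timestamps are an error (collapse them upstream, as [read_gps_csv()] does).
#'
#' @param fixes Data frame with columns `t` (POSIXct), `x`, `y` (projected
#'   metres) and optionally `pdop`.
#' @param meta An [animal_meta()] object.
#' @return An object of class `trajectory`: a list with elements `meta` and
#'   `fixes`.
#' @export
trajectory <- function(fixes, meta) {
  stopifnot(inherits(meta, "animal_meta"), is.data.frame(fixes),
            all(c("t", "x", "y") %in% names(fixes)))
  if (!"pdop" %in% names(fixes)) fixes$pdop <- NA_real_
  if (!all(is.finite(fixes$x)) || !all(is.finite(fixes$y))) {
    stop("non-finite coordinates in fixes", call. = FALSE)
  }
  fixes <- fixes[order(fixes$t), c("t", "x", "y", "pdop")]
  if (anyDuplicated(fixes$t)) {
    stop("duplicate timestamps within a trajectory", call. = FALSE)
  }
  rownames(fixes) <- NULL
  structure(list(meta = meta, fixes = fixes), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s (%s), %d fixes", x$meta$animal_id,
              x$meta$status, nrow(x$fixes)))
  if (nrow(x$fixes) > 0) {
    cat(sprintf(", %s to %s", format(min(x$fixes$t)), format(max(x$fixes$t))))
  }
  cat("\n")
  invisible(x)
}

#' Number of fixes in a trajectory
#' @param traj A [trajectory()].
#' @return Integer fix count.
#' @export
n_fixes <- function(traj) nrow(traj$fixes)

#' Read GPS fixes from CSV
#'
#' Reads a projected GPS telemetry table (one row per fix) and splits it into
#' one [trajectory()] per animal. Rows are time-sorted within animal;
#' duplicate (animal, timestamp) rows are collapsed to the first occurrence
#' with a warning.
#'
#' @param path CSV file with a header.
#' @param column_map Named character vector mapping the canonical names
#'   `animal_id`, `timestamp`, `x`, `y`, `pdop` to the file's column names.
#' @param tz Time zone for timestamp parsing (timestamps should be ISO-8601).
#' @return Named list of `trajectory` objects (metadata minimal; attach
#'   richer metadata with [read_animal_meta()] / [set_meta()]).
#' @export
read_gps_csv <- function(path,
                         column_map = c(animal_id = "animal_id",
                                        timestamp = "timestamp",
                                        x = "x", y = "y", pdop = "pdop"),
                         tz = "UTC") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "timestamp", "x", "y")
  missing_cols <- setdiff(unname(column_map[req]), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts_chr <- as.character(raw[[column_map[["timestamp"]]]])
  t <- rep(as.POSIXct(NA), length(ts_chr))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(t))
    if (length(idx) == 0) break
    t[idx] <- as.POSIXct(strptime(ts_chr[idx], fmt, tz = tz))
  }
  bad <- which(is.na(t) & !is.na(ts_chr) & nzchar(ts_chr))
  if (length(bad) > 0) {
    stop("unparseable timestamp(s) at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  pdop_col <- column_map[["pdop"]]
  df <- data.frame(animal_id = as.character(raw[[column_map[["animal_id"]]]]),
                   t = t,
                   x = as.numeric(raw[[column_map[["x"]]]]),
                   y = as.numeric(raw[[column_map[["y"]]]]),
                   pdop = if (!is.na(pdop_col) && pdop_col %in% names(raw))
                     as.numeric(raw[[pdop_col]]) else NA_real_)
  dup <- duplicated(df[c("animal_id", "t")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (animal, timestamp) row(s) collapsed to ",
            "first occurrence", call. = FALSE)
    df <- df[!dup, ]
  }
  out <- lapply(split(df, df$animal_id), function(d) {
    trajectory(d[c("t", "x", "y", "pdop")],
               animal_meta(d$animal_id[1], "resident"))
  })
  out[order(names(out))]
}

#' Read animal metadata from CSV
#'
#' Expected columns: `animal_id`, `status`, `release_habitat`, `release_x`,
#' `release_y`, `capture_x`, `capture_y`. An optional censor CSV holds
#' columns `animal_id`, `start`, `end` (ISO-8601).
#'
#' @param path Metadata CSV path.
#' @param censor_path Optional censor-window CSV path.
#' @param tz Time zone for censor timestamps.
#' @return Named list of [animal_meta()] objects.
#' @export
read_animal_meta <- function(path, censor_path = NULL, tz = "UTC") {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "status", "release_habitat", "release_x", "release_y",
           "capture_x", "capture_y")
  if (!all(req %in% names(m))) {
    stop("metadata CSV must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  cens <- NULL
  if (!is.null(censor_path) && file.exists(censor_path)) {
    cc <- utils::read.csv(censor_path, stringsAsFactors = FALSE)
    cc$start <- as.POSIXct(cc$start, tz = tz)
    cc$end <- as.POSIXct(cc$end, tz = tz)
    cens <- split(cc, cc$animal_id)
  }
  out <- lapply(seq_len(nrow(m)), function(i) {
    id <- as.character(m$animal_id[i])
    animal_meta(id, m$status[i], m$release_habitat[i],
                release_xy = c(m$release_x[i], m$release_y[i]),
                capture_xy = c(m$capture_x[i], m$capture_y[i]),
                capture_habitat = if ("capture_habitat" %in% names(m))
                  m$capture_habitat[i] else NA_character_,
                censor_windows = if (!is.null(cens)) cens[[id]] else NULL)
  })
  names(out) <- as.character(m$animal_id)
  out
}

#' Attach metadata to a trajectory
#' @param traj A [trajectory()].
#' @param meta An [animal_meta()].
#' @return The trajectory with `meta` replaced.
#' @export
set_meta <- function(traj, meta) {
  stopifnot(inherits(traj, "trajectory"), inherits(meta, "animal_meta"))
  traj$meta <- meta
  traj
}

#' Remove poor-quality fixes by PDOP
#'
#' Fixes with PDOP strictly greater than `cfg$pdop_max` are removed; fixes
#' with missing PDOP are retained (absence of the diagnostic is not evidence
#' of a poor fix).
#'
#' @param traj A [trajectory()].
#' @param cfg A [preprocess_config()].
#' @return Filtered trajectory.
#' @export
filter_pdop <- function(traj, cfg = preprocess_config()) {
  keep <- is.na(traj$fixes$pdop) | traj$fixes$pdop <= cfg$pdop_max
  if (!any(keep)) {
    warning("all fixes removed by PDOP filter for ", traj$meta$animal_id,
            call. = FALSE)
  }
  traj$fixes <- traj$fixes[keep, ]
  rownames(traj$fixes) <- NULL
  traj
}

#' Subsample a trajectory to a common interval
#'
#' Greedy forward thinning to the target cadence: the first fix is kept, then
#' the fix closest to (last kept time + target interval) within the tolerance
#' is kept, repeatedly. Fixes collected at finer cadence (15 min, 1 h) are
#' thinned; nothing is ever interpolated, and gaps are preserved (after a gap
#' the first available fix is kept and the clock restarts from it).
#'
#' @inheritParams filter_pdop
#' @return Thinned trajectory at roughly the target cadence.
#' @export
resample_to_interval <- function(traj, cfg = preprocess_config()) {
  tt <- as.numeric(traj$fixes$t)
  n <- length(tt)
  if (n <= 1) return(traj)
  tau <- cfg$target_interval_s
  tol <- cfg$interval_tolerance_s
  keep <- logical(n)
  keep[1] <- TRUE
  i <- 1
  while (TRUE) {
    target <- tt[i] + tau
    cand <- which(tt >= target - tol & tt <= target + tol & seq_len(n) > i)
    if (length(cand) > 0) {
      j <- cand[which.min(abs(tt[cand] - target))]
    } else {
      later <- which(tt > target + tol)
      if (length(later) == 0) break
      j <- later[1]
    }
    keep[j] <- TRUE
    i <- j
  }
  traj$fixes <- traj$fixes[keep, ]
  rownames(traj$fixes) <- NULL
  traj
}

#' Step geometry of a trajectory
#'
#' Computes the n-1 steps between consecutive fixes: length, duration,
#' heading, and signed turning angle (difference of consecutive headings
#' wrapped to (-pi, pi]). The first step's turning angle is undefined, as is
#' any turning angle that follows a zero-displacement step (whose heading is
#' undefined).
#'
#' @param traj A [trajectory()] with at least 2 fixes (fewer returns an
#'   empty data frame).
#' @return Data frame with columns `t0`, `t1`, `x0`, `y0`, `x1`, `y1`,
#'   `duration_s`, `length`, `heading`, `turning_angle`.
#' @export
compute_steps <- function(traj) {
  f <- traj$fixes
  n <- nrow(f)
  empty <- data.frame(t0 = as.POSIXct(character(), tz = "UTC"),
                      t1 = as.POSIXct(character(), tz = "UTC"),
                      x0 = numeric(), y0 = numeric(), x1 = numeric(),
                      y1 = numeric(), duration_s = numeric(),
                      length = numeric(), heading = numeric(),
                      turning_angle = numeric())
  if (n < 2) return(empty)
  dx <- diff(f$x)
  dy <- diff(f$y)
  len <- sqrt(dx^2 + dy^2)
  heading <- ifelse(len > 0, atan2(dy, dx), NA_real_)
  ta <- c(NA_real_, wrap_angle(diff(heading)))
  data.frame(t0 = f$t[-n], t1 = f$t[-1], x0 = f$x[-n], y0 = f$y[-n],
             x1 = f$x[-1], y1 = f$y[-1],
             duration_s = diff(as.numeric(f$t)),
             length = len, heading = heading, turning_angle = ta)
}

#' Wrap angles to (-pi, pi]
#' @param a Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(a) {
  w <- a - 2 * pi * floor((a + pi) / (2 * pi))
  w[!is.na(w) & w <= -pi] <- pi  # boundary maps to +pi
  w
}

#' Detect a homing return of a translocated animal
#'
#' A translocated animal counts as having returned to its original home
#' range the first time a fix falls within `homing_radius_m` (default 1.6 km,
#' the radius of the average resident home range) of the capture location,
#' provided this happens within `homing_window_days` (default 10) of release.
#'
#' @inheritParams filter_pdop
#' @return The timestamp of the first qualifying fix, or `NULL`.
#' @export
detect_homing_return <- function(traj, cfg = preprocess_config()) {
  if (traj$meta$status != "translocated") {
    stop("detect_homing_return() applies to translocated animals only",
         call. = FALSE)
  }
  f <- traj$fixes
  if (nrow(f) == 0) return(NULL)
  release_t <- f$t[1]
  d <- sqrt((f$x - traj$meta$capture_xy[1])^2 +
            (f$y - traj$meta$capture_xy[2])^2)
  within <- d <= cfg$homing_radius_m &
    as.numeric(f$t) - as.numeric(release_t) <= cfg$homing_window_days * 86400
  if (!any(within)) return(NULL)
  f$t[which(within)[1]]
}

#' Apply censoring, homing reclassification and horizon truncation
#'
#' Removes fixes inside the animal's censor windows; if a homing return time
#' is supplied, removes fixes from release up to (but excluding) the return
#' and reclassifies the animal as a resident based at its capture site; then
#' truncates the series to `truncate_days` from its (possibly re-based)
#' first fix.
#'
#' @inheritParams filter_pdop
#' @param homing_time Timestamp from [detect_homing_return()], or `NULL`.
#' @return Censored, truncated trajectory.
#' @export
apply_censoring <- function(traj, homing_time = NULL,
                            cfg = preprocess_config()) {
  f <- traj$fixes
  cw <- traj$meta$censor_windows
  if (!is.null(cw) && nrow(cw) > 0 && nrow(f) > 0) {
    drop <- rep(FALSE, nrow(f))
    for (k in seq_len(nrow(cw))) {
      drop <- drop | (f$t >= cw$start[k] & f$t <= cw$end[k])
    }
    f <- f[!drop, ]
  }
  if (!is.null(homing_time) && nrow(f) > 0) {
    f <- f[f$t >= homing_time, ]
    traj$meta$status <- "resident"
    # returned home: the animal is a resident of its original range
    traj$meta$release_xy <- traj$meta$capture_xy
    if (!is.na(traj$meta$capture_habitat)) {
      traj$meta$release_habitat <- traj$meta$capture_habitat
    }
  }
  if (nrow(f) > 0) {
    f <- f[as.numeric(f$t) - as.numeric(f$t[1]) < cfg$truncate_days * 86400, ]
  }
  rownames(f) <- NULL
  traj$fixes <- f
  traj
}

#' Full preprocessing pipeline for one trajectory
#'
#' PDOP filter, interval subsampling, homing detection (translocated animals
#' only), censoring and 90-day truncation, in the order the analysis
#' protocol prescribes.
#'
#' @inheritParams filter_pdop
#' @return Preprocessed trajectory.
#' @export
preprocess_trajectory <- function(traj, cfg = preprocess_config()) {
  traj <- filter_pdop(traj, cfg)
  traj <- resample_to_interval(traj, cfg)
  homing <- NULL
  if (traj$meta$status == "translocated" &&
      all(is.finite(traj$meta$capture_xy))) {
    homing <- detect_homing_return(traj, cfg)
  }
  apply_censoring(traj, homing, cfg)
}

#' Calendar day index of timestamps relative to release
#'
#' Day 1 is the local calendar day (in `tz`) of the release (first fix).
#'
#' @param t POSIXct vector.
#' @param release_t POSIXct scalar.
#' @param tz Time zone defining midnight boundaries.
#' @return Integer day indices (1-based).
#' @export
day_index <- function(t, release_t, tz = "UTC") {
  as.integer(as.Date(t, tz = tz) - as.Date(release_t, tz = tz)) + 1L
}
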