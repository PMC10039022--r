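#' Moving-window configuration
#'
#' @param half_width_days Days included on each side of the focal day
#'   (default 3, i.e. a 7-day window).
#' @param horizon_days Monitoring horizon in days post release.
#' @param expected_fixes_per_day Nominal fixes per day at the target cadence.
#' @param tz Time zone defining calendar-day boundaries.
#' @return A list of class `window_config`.
#' @export
window_config <- function(half_width_days = 3, horizon_days = 90,
                          expected_fixes_per_day = 12, tz = "UTC") {
  stopifnot(half_width_days >= 0, horizon_days >= 1)
  structure(list(half_width_days = as.integer(half_width_days),
                 horizon_days = as.integer(horizon_days),
                 expected_fixes_per_day = as.integer(expected_fixes_per_day),
                 tz = tz),
            class = "window_config")
}

#' Day interval of the moving window around a focal day
#'
#' Day `d`'s window spans `d - 3` to `d + 3` (by default), truncated at the
#' series edges, so e.g. day 4 is summarised over days 1 through 7.
#'
#' @param day Focal day index (1-based).
#' @param cfg A [window_config()].
#' @param last_day Last day with data.
#' @return Integer vector `c(first, last)`.
#' @export
window_days <- function(day, cfg = window_config(), last_day) {
  if (day < 1 || day > last_day) {
    stop("day must lie in [1, last_day]", call. = FALSE)
  }
  as.integer(c(max(1, day - cfg$half_width_days),
               min(last_day, day + cfg$half_width_days)))
}

#' Moving-window dBBMM core and range areas
#'
#' The dynamic motion-variance profile is estimated once over the entire
#' monitoring period; the UD for each day is then built from the bridges
#' whose fixes fall inside that day's 7-day window, and summarised by its
#' 50% (core) and 95% (range) isopleth areas. Days whose window holds fewer
#' fixes than the dBBMM window size yield missing values.
#'
#' @param traj A preprocessed [trajectory()].
#' @param cfg A [window_config()].
#' @param dcfg A [dbbmm_config()].
#' @param profile Optional precomputed [dynamic_variance_profile()].
#' @return Data frame: `day`, `core_area_ha`, `range_area_ha`,
#'   `n_fixes_window`.
#' @export
windowed_ud_areas <- function(traj, cfg = window_config(),
                              dcfg = dbbmm_config(), profile = NULL) {
  f <- traj$fixes
  if (nrow(f) == 0) {
    return(data.frame(day = integer(0), core_area_ha = numeric(0),
                      range_area_ha = numeric(0),
                      n_fixes_window = integer(0)))
  }
  day <- day_index(f$t, f$t[1], cfg$tz)
  last_day <- min(max(day), cfg$horizon_days)
  if (is.null(profile) && nrow(f) >= 2) {
    profile <- dynamic_variance_profile(traj, dcfg)
  }
  out <- data.frame(day = seq_len(last_day), core_area_ha = NA_real_,
                    range_area_ha = NA_real_, n_fixes_window = 0L)
  for (d in seq_len(last_day)) {
    wd <- window_days(d, cfg, last_day)
    idx <- which(day >= wd[1] & day <= wd[2])
    out$n_fixes_window[d] <- length(idx)
    if (length(idx) < dcfg$window_size) next
    sub <- traj
    sub$fixes <- f[idx, ]
    sub_profile <- list(sigma2 = profile$sigma2[idx[1]:(idx[length(idx)] - 1)])
    ud <- compute_ud(sub, sub_profile, dcfg)
    ar <- isopleth_area(ud, c(0.5, 0.95))
    out$core_area_ha[d] <- ar[[1]]
    out$range_area_ha[d] <- ar[[2]]
  }
  out
}

#' Daily mean distance from the release site
#'
#' Per calendar day, the mean Euclidean distance of that day's fixes to the
#' release location (for residents, the capture/release site).
#'
#' @param traj A preprocessed [trajectory()].
#' @param tz Time zone defining day boundaries.
#' @return Data frame: `day`, `mean_dist_release_m`, `n_fixes`.
#' @export
distance_from_release <- function(traj, tz = "UTC") {
  f <- traj$fixes
  rel <- traj$meta$release_xy
  if (!all(is.finite(rel))) stop("release_xy is not set", call. = FALSE)
  day <- day_index(f$t, f$t[1], tz)
  d <- sqrt((f$x - rel[1])^2 + (f$y - rel[2])^2)
  agg <- data.frame(day = sort(unique(day)))
  agg$mean_dist_release_m <- as.numeric(
    tapply(d, day, mean)[as.character(agg$day)])
  agg$n_fixes <- as.integer(table(day)[as.character(agg$day)])
  agg
}

#' Daily distance travelled and net squared displacement
#'
#' Daily distance is the sum of the lengths of steps whose terminal fix
#' falls on that day; net squared displacement (NSD) is the squared distance
#' of the day's last fix from the release site.
#'
#' @inheritParams distance_from_release
#' @return Data frame: `day`, `daily_distance_m`, `nsd_m2`.
#' @export
daily_distance <- function(traj, tz = "UTC") {
  f <- traj$fixes
  rel <- traj$meta$release_xy
  day <- day_index(f$t, f$t[1], tz)
  steps <- compute_steps(traj)
  agg <- data.frame(day = sort(unique(day)))
  if (nrow(steps) > 0) {
    step_day <- day_index(steps$t1, f$t[1], tz)
    dd <- tapply(steps$length, step_day, sum)
    agg$daily_distance_m <- ifelse(as.character(agg$day) %in% names(dd),
                                   as.numeric(dd[as.character(agg$day)]), 0)
  } else {
    agg$daily_distance_m <- 0
  }
  last_of_day <- tapply(seq_along(day), day, max)
  li <- as.integer(last_of_day[as.character(agg$day)])
  agg$nsd_m2 <- (f$x[li] - rel[1])^2 + (f$y[li] - rel[2])^2
  agg
}

#' Full daily metric suite for one animal
#'
#' Combines the moving-window dBBMM areas with the daily distance metrics
#' into one table of daily space-use metrics.
#'
#' @inheritParams windowed_ud_areas
#' @return Data frame: `animal_id`, `status`, `release_habitat`, `day`,
#'   `core_area_ha`, `range_area_ha`, `mean_dist_release_m`,
#'   `daily_distance_m`, `nsd_m2`, `n_fixes`.
#' @export
compute_daily_metrics <- function(traj, cfg = window_config(),
                                  dcfg = dbbmm_config(), profile = NULL) {
  areas <- windowed_ud_areas(traj, cfg, dcfg, profile)
  dist <- distance_from_release(traj, cfg$tz)
  trav <- daily_distance(traj, cfg$tz)
  out <- merge(areas, dist, by = "day", all.x = TRUE)
  out <- merge(out, trav, by = "day", all.x = TRUE)
  out <- out[out$day <= cfg$horizon_days, ]
  data.frame(animal_id = traj$meta$animal_id, status = traj$meta$status,
             release_habitat = traj$meta$release_habitat, out,
             stringsAsFactors = FALSE)
}

#' Group mean and standard error series
#'
#' Summarises per-animal daily metrics by group (status x release habitat)
#' and day: mean over the animals with data that day, between-animal
#' standard error (sd / sqrt(n), reported only when n >= 2), and n.
#'
#' @param metrics Row-bound output of [compute_daily_metrics()] for a
#'   cohort.
#' @param metric_cols Metric columns to summarise.
#' @return Long data frame: `status`, `release_habitat`, `day`, `metric`,
#'   `mean`, `se`, `n`.
#' @export
group_series <- function(metrics,
                         metric_cols = c("core_area_ha", "range_area_ha",
                                         "mean_dist_release_m",
                                         "daily_distance_m", "nsd_m2")) {
  groups <- unique(metrics[c("status", "release_habitat")])
  out <- list()
  for (g in seq_len(nrow(groups))) {
    sub <- metrics[metrics$status == groups$status[g] &
                   metrics$release_habitat == groups$release_habitat[g], ]
    if (nrow(sub) == 0) {
      warning("empty group omitted: ", groups$status[g], " x ",
              groups$release_habitat[g], call. = FALSE)
      next
    }
    for (m in metric_cols) {
      v <- sub[[m]]
      ok <- !is.na(v)
      if (!any(ok)) {
        warning("group ", groups$status[g], " x ",
                groups$release_habitat[g], " has no data for ", m,
                call. = FALSE)
        next
      }
      days <- sort(unique(sub$day[ok]))
      mn <- tapply(v[ok], sub$day[ok], mean)
      nn <- tapply(v[ok], sub$day[ok], length)
      sdv <- tapply(v[ok], sub$day[ok], stats::sd)
      se <- ifelse(nn >= 2, sdv / sqrt(nn), NA_real_)
      out[[length(out) + 1]] <- data.frame(
        status = groups$status[g],
        release_habitat = groups$release_habitat[g],
        day = days, metric = m,
        mean = as.numeric(mn[as.character(days)]),
        se = as.numeric(se[as.character(days)]),
        n = as.integer(nn[as.character(days)]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Exploration-to-exploitation transition of a translocated group
#'
#' The crossing day is the first day on which the translocated group's mean
#' 95% dBBMM range area reaches (drops to or below) the resident reference.
#' The crossing day is the last exploration day; exploitation starts the
#' following day. The resident reference is, by default, the grand mean of
#' the resident group's daily mean range areas over the horizon; a
#' day-matched comparison is available as an alternative.
#'
#' @param translocated [group_series()] rows for the translocated group
#'   (metric `range_area_ha`).
#' @param resident_reference [group_series()] rows for the corresponding
#'   resident group (metric `range_area_ha`).
#' @param horizon_days Monitoring horizon.
#' @param reference `"grand"` (default) or `"daymatched"`.
#' @return Object of class `phase_assignment`: list with `crossing_day`
#'   (NA if never reached), `transition_day` (first exploitation day;
#'   `horizon_days + 1` if never reached), `reached` flag, per-day `phase`
#'   factor, and the reference value used.
#' @export
detect_phase_transition <- function(translocated, resident_reference,
                                    horizon_days = 90,
                                    reference = c("grand", "daymatched")) {
  reference <- match.arg(reference)
  tr <- translocated[translocated$metric == "range_area_ha" &
                     !is.na(translocated$mean), ]
  rs <- resident_reference[resident_reference$metric == "range_area_ha" &
                           !is.na(resident_reference$mean), ]
  if (nrow(tr) == 0 || nrow(rs) == 0) {
    stop("need non-missing range-area series for both groups", call. = FALSE)
  }
  tr <- tr[order(tr$day), ]
  if (reference == "grand") {
    ref_val <- mean(rs$mean[rs$day <= horizon_days])
    crossed <- tr$mean <= ref_val
  } else {
    ref_map <- stats::setNames(rs$mean, rs$day)
    ref_val <- ref_map[as.character(tr$day)]
    crossed <- !is.na(ref_val) & tr$mean <= ref_val
    ref_val <- mean(rs$mean[rs$day <= horizon_days])
  }
  if (any(crossed)) {
    crossing_day <- tr$day[which(crossed)[1]]
    transition_day <- crossing_day + 1L
    reached <- TRUE
  } else {
    crossing_day <- NA_integer_
    transition_day <- as.integer(horizon_days + 1L)
    reached <- FALSE
  }
  phase <- factor(ifelse(seq_len(horizon_days) >= transition_day,
                         "exploitation", "exploration"),
                  levels = c("exploration", "exploitation"))
  structure(list(status = "translocated",
                 release_habitat = tr$release_habitat[1],
                 crossing_day = crossing_day,
                 transition_day = transition_day,
                 reached = reached, phase = phase,
                 resident_reference_ha = unname(ref_val)),
            class = "phase_assignment")
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat(sprintf(paste0("<phase_assignment> %s group: %s"),
              x$release_habitat,
              if (x$reached) {
                sprintf("reached resident level on day %d (exploitation from day %d)",
                        x$crossing_day, x$transition_day)
              } else "never reached the resident reference"), "\n")
  invisible(x)
}

#' Phase of a day under a phase assignment
#' @param pa A `phase_assignment`.
#' @param day Integer day indices.
#' @return Character vector `"exploration"`/`"exploitation"`.
#' @export
phase_of_day <- function(pa, day) {
  ifelse(day >= pa$transition_day, "exploitation", "exploration")
}
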