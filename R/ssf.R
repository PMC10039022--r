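#' Step-selection function configuration
#'
#' @param n_random_steps Random (available) steps generated per used step.
#' @param reference_habitat Habitat class absorbed into the baseline, so
#'   reported coefficients are selection relative to it.
#' @param diel_mode `"solar"` classifies fixes by sun altitude at the study
#'   site; `"fixed"` uses a fixed clock window.
#' @param fixed_day_window Character `c(start, end)` "HH:MM" clock window
#'   counted as diurnal in fixed mode.
#' @param site_latlon Latitude/longitude (degrees, east positive) for solar
#'   mode.
#' @param tz Time zone for clock-based classification.
#' @return A list of class `ssf_config`.
#' @export
ssf_config <- function(n_random_steps = 20, reference_habitat = "upland_pine",
                       diel_mode = c("solar", "fixed"),
                       fixed_day_window = c("06:00", "18:00"),
                       site_latlon = c(33.3, -81.7), tz = "UTC") {
  diel_mode <- match.arg(diel_mode)
  stopifnot(n_random_steps >= 1)
  if (diel_mode == "solar" &&
      (length(site_latlon) != 2 || any(!is.finite(site_latlon)))) {
    stop("solar diel mode requires site_latlon", call. = FALSE)
  }
  structure(list(n_random_steps = as.integer(n_random_steps),
                 reference_habitat = reference_habitat,
                 diel_mode = diel_mode,
                 fixed_day_window = fixed_day_window,
                 site_latlon = site_latlon, tz = tz),
            class = "ssf_config")
}

#' Solar altitude
#'
#' Standard low-precision solar-position formulas (fractional-year series
#' for declination and the equation of time, then the hour angle from true
#' solar time).
#'
#' @param t POSIXct times (any time zone; converted to UTC internally).
#' @param lat,lon Degrees; longitude east positive.
#' @return Solar altitude above the horizon, degrees.
#' @export
solar_altitude <- function(t, lat, lon) {
  tu <- as.POSIXlt(t, tz = "UTC")
  doy <- tu$yday + 1
  frac_h <- tu$hour + tu$min / 60 + tu$sec / 3600
  g <- 2 * pi / 365 * (doy - 1 + (frac_h - 12) / 24)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                      0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  tst <- (frac_h * 60 + eqtime + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * pi / 180
  latr <- lat * pi / 180
  cos_zen <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  asin(pmin(1, pmax(-1, cos_zen))) * 180 / pi
}

#' Classify fixes as diurnal or nocturnal
#'
#' Solar mode: diurnal iff the sun is strictly above the horizon at the
#' study site. Fixed mode: diurnal iff the local clock time falls inside
#' the configured day window (start inclusive, end exclusive).
#'
#' @param t POSIXct times.
#' @param cfg An [ssf_config()].
#' @return Character vector `"diurnal"`/`"nocturnal"`.
#' @export
classify_diel <- function(t, cfg = ssf_config()) {
  if (cfg$diel_mode == "solar") {
    alt <- solar_altitude(t, cfg$site_latlon[1], cfg$site_latlon[2])
    ifelse(alt > 0, "diurnal", "nocturnal")
  } else {
    clock <- format(t, "%H:%M", tz = cfg$tz)
    ifelse(clock >= cfg$fixed_day_window[1] & clock < cfg$fixed_day_window[2],
           "diurnal", "nocturnal")
  }
}

# kernel stratum key for one animal-day
kernel_key <- function(status, release_habitat, phase) {
  ifelse(status == "resident", "resident",
         paste("translocated", release_habitat, phase, sep = "."))
}

#' Per-step table for a cohort
#'
#' Expands each preprocessed trajectory into its steps, annotated with day,
#' release-relative week, diel period, behavioural phase (from the group's
#' phase assignment; residents are always "exploitation"), previous heading,
#' and the empirical-kernel stratum the step belongs to.
#'
#' @param trajs List of preprocessed [trajectory()] objects.
#' @param phases Named list of [detect_phase_transition()] results keyed by
#'   release habitat (for translocated groups).
#' @param cfg An [ssf_config()].
#' @param tz Time zone for day boundaries.
#' @return Data frame, one row per step.
#' @export
build_step_table <- function(trajs, phases = list(), cfg = ssf_config(),
                             tz = "UTC") {
  rows <- lapply(trajs, function(tr) {
    st <- compute_steps(tr)
    if (nrow(st) == 0) return(NULL)
    day <- day_index(st$t1, tr$fixes$t[1], tz)
    phase <- rep("exploitation", nrow(st))
    if (tr$meta$status == "translocated") {
      pa <- phases[[tr$meta$release_habitat]]
      if (is.null(pa)) {
        stop("no phase assignment for release habitat ",
             tr$meta$release_habitat, call. = FALSE)
      }
      phase <- phase_of_day(pa, day)
    }
    data.frame(animal_id = tr$meta$animal_id, status = tr$meta$status,
               release_habitat = tr$meta$release_habitat,
               step = seq_len(nrow(st)), day = day,
               week = (day - 1L) %/% 7L + 1L,
               t1 = st$t1, x0 = st$x0, y0 = st$y0, x1 = st$x1, y1 = st$y1,
               length = st$length, heading = st$heading,
               turning_angle = st$turning_angle,
               prev_heading = c(NA_real_, st$heading[-nrow(st)]),
               diel = classify_diel(st$t1, cfg),
               phase = phase,
               kernel = kernel_key(tr$meta$status, tr$meta$release_habitat,
                                   phase),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Empirical movement kernels by stratum
#'
#' Builds the empirical step-length and turning-angle samples for each
#' kernel stratum: one pooled kernel for residents regardless of habitat,
#' and one per release habitat x phase for translocated animals. Steps with
#' undefined turning angles are excluded from the samples.
#'
#' @param step_table Output of [build_step_table()].
#' @return Named list of class `move_kernels`; each element holds
#'   `animal_id`, `length` and `angle` vectors.
#' @export
build_kernels <- function(step_table) {
  ok <- !is.na(step_table$turning_angle) & !is.na(step_table$length)
  st <- step_table[ok, ]
  out <- lapply(split(st, st$kernel), function(d) {
    list(animal_id = d$animal_id, length = d$length, angle = d$turning_angle)
  })
  structure(out, class = "move_kernels")
}

#' Extract a kernel sample excluding the focal animal
#'
#' @param kernels A `move_kernels` list from [build_kernels()].
#' @param key Kernel stratum key.
#' @param exclude_animal Focal animal id whose own steps are removed.
#' @return List with `length` and `angle` sample vectors.
#' @export
kernel_sample <- function(kernels, key, exclude_animal = NULL) {
  k <- kernels[[key]]
  if (is.null(k)) stop("no kernel for stratum ", key, call. = FALSE)
  keep <- if (is.null(exclude_animal)) rep(TRUE, length(k$length)) else
    k$animal_id != exclude_animal
  n <- sum(keep)
  if (n < 2) stop("kernel ", key, " has fewer than 2 steps after excluding ",
                  exclude_animal, call. = FALSE)
  if (n < 30) warning("kernel ", key, " has only ", n,
                      " steps after exclusion", call. = FALSE)
  list(length = k$length[keep], angle = k$angle[keep])
}

#' Generate random available steps for one used step
#'
#' Samples `n` (length, angle) pairs, each component drawn independently and
#' uniformly with replacement from the kernel's empirical samples; the
#' endpoint of each random step starts at the used step's origin with
#' heading `prev_heading + angle`.
#'
#' @param x0,y0 Origin of the used step, metres.
#' @param prev_heading Heading of the preceding step, radians.
#' @param kern List with `length` and `angle` samples ([kernel_sample()]).
#' @param n Number of random steps.
#' @return Data frame with `x1`, `y1`, `length`, `angle` for the `n`
#'   random alternatives.
#' @export
generate_random_steps <- function(x0, y0, prev_heading, kern, n) {
  if (is.na(prev_heading)) {
    stop("previous heading undefined; skip this stratum", call. = FALSE)
  }
  # index-based resampling (sample(x, ...) would misbehave on length-1 x)
  len <- kern$length[sample.int(length(kern$length), n, replace = TRUE)]
  ang <- kern$angle[sample.int(length(kern$angle), n, replace = TRUE)]
  head <- wrap_angle(prev_heading + ang)
  data.frame(x1 = x0 + len * cos(head), y1 = y0 + len * sin(head),
             length = len, angle = ang)
}

#' Assemble step-selection choice sets for a cohort
#'
#' For every used step with a defined previous heading, draws
#' `n_random_steps` random alternatives from the animal's phase- and
#' habitat-stratified empirical kernel (excluding the focal animal's own
#' steps), annotates every endpoint with the landcover class, marks
#' endpoints in excluded classes or off the raster invalid, and drops
#' strata whose used step is invalid. Random-number use is seeded per
#' animal, so choice sets are reproducible and independent of processing
#' order.
#'
#' @param step_table Output of [build_step_table()].
#' @param kernels Output of [build_kernels()].
#' @param landscape A [landscape_raster()].
#' @param cfg An [ssf_config()].
#' @param seed Integer seed.
#' @return Long data frame, one row per alternative: `stratum_id`,
#'   `animal_id`, `status`, `release_habitat`, `phase`, `diel`, `week`,
#'   `used`, `x1`, `y1`, `length`, `habitat`. Dropped-strata counts are
#'   attached as attribute `dropped`.
#' @export
assemble_choice_sets <- function(step_table, kernels, landscape,
                                 cfg = ssf_config(), seed = 1) {
  n_rand <- cfg$n_random_steps
  animals <- sort(unique(step_table$animal_id))
  pieces <- list()
  dropped <- c(no_heading = 0L, used_invalid = 0L)
  for (a in animals) {
    st <- step_table[step_table$animal_id == a, ]
    usable <- !is.na(st$prev_heading)
    dropped[["no_heading"]] <- dropped[["no_heading"]] + sum(!usable)
    st <- st[usable, ]
    if (nrow(st) == 0) next
    set.seed(child_seed(seed, a))
    kern_cache <- list()
    res <- vector("list", nrow(st))
    for (i in seq_len(nrow(st))) {
      key <- st$kernel[i]
      if (is.null(kern_cache[[key]])) {
        kern_cache[[key]] <- kernel_sample(kernels, key, a)
      }
      rnd <- generate_random_steps(st$x0[i], st$y0[i], st$prev_heading[i],
                                   kern_cache[[key]], n_rand)
      res[[i]] <- data.frame(
        stratum_id = paste0(a, "_", st$step[i]),
        animal_id = a, status = st$status[i],
        release_habitat = st$release_habitat[i], phase = st$phase[i],
        diel = st$diel[i], week = st$week[i],
        used = c(1L, rep(0L, n_rand)),
        x1 = c(st$x1[i], rnd$x1), y1 = c(st$y1[i], rnd$y1),
        length = c(st$length[i], rnd$length),
        angle = c(st$turning_angle[i], rnd$angle),
        stringsAsFactors = FALSE)
    }
    pieces[[a]] <- do.call(rbind, res)
  }
  cs <- do.call(rbind, pieces)
  rownames(cs) <- NULL
  cs$habitat <- class_at(landscape, cs$x1, cs$y1)
  invalid <- is.na(cs$habitat) | cs$habitat == "excluded"
  bad_strata <- unique(cs$stratum_id[invalid & cs$used == 1L])
  dropped[["used_invalid"]] <- length(bad_strata)
  cs <- cs[!(cs$stratum_id %in% bad_strata) & !invalid, ]
  # a usable stratum needs the used step plus at least one alternative
  tab <- table(cs$stratum_id)
  cs <- cs[cs$stratum_id %in% names(tab)[tab >= 2], ]
  rownames(cs) <- NULL
  attr(cs, "dropped") <- dropped
  cs
}

#' Add model covariates to a choice-set table
#'
#' Adds the dummy variables the candidate models use: `hb` (bottomland),
#' `hg` (grassland; both relative to the reference habitat), `tr`
#' (translocated), `rh` (released in bottomland), `noct` (nocturnal), and
#' `sl_km` (step length, km).
#'
#' @param cs Output of [assemble_choice_sets()].
#' @param cfg An [ssf_config()].
#' @return `cs` with covariate columns appended.
#' @export
prepare_ssf_covariates <- function(cs, cfg = ssf_config()) {
  cs$hb <- as.integer(cs$habitat == "bottomland")
  cs$hg <- as.integer(cs$habitat == "grassland")
  cs$tr <- as.integer(cs$status == "translocated")
  cs$rh <- as.integer(cs$release_habitat == "bottomland")
  cs$noct <- as.integer(cs$diel == "nocturnal")
  cs$sl_km <- cs$length / 1000
  cs$cos_ta <- cos(cs$angle)  # movement-control covariate (persistence)
  cs
}

#' Conditional logistic log-likelihood by direct enumeration
#'
#' Evaluates `sum_s [x_used beta - log sum_alt exp(x_alt beta)]` directly
#' over the strata. Used as an independent cross-check of fitted models.
#'
#' @param X Numeric model matrix (no intercept).
#' @param used 0/1 vector marking the used alternative.
#' @param stratum Stratum identifier vector.
#' @param beta Coefficient vector.
#' @return Log-likelihood value.
#' @export
clogit_loglik <- function(X, used, stratum, beta) {
  lp <- as.numeric(X %*% beta)
  m <- tapply(lp, stratum, max)[as.character(stratum)]
  denom <- tapply(exp(lp - m), stratum, sum)
  sum(lp[used == 1]) -
    sum(log(denom) + tapply(lp, stratum, max))
}

#' Fit a conditional logistic step-selection model
#'
#' Maximises the conditional-logit likelihood (one used step per stratum of
#' 1 + n random alternatives) via [survival::clogit()]; standard errors are
#' cluster-robust by animal. With a single case per stratum all partial-
#' likelihood tie methods coincide.
#'
#' @param cs Covariate-prepared choice sets ([prepare_ssf_covariates()]).
#' @param covars Character vector of model terms (may include `:`
#'   interactions of the prepared dummies).
#' @param name Model label.
#' @return Object of class `ssf_fit`: coefficients, naive and robust SEs,
#'   log-likelihood, AIC, stratum count and the underlying fit.
#' @export
fit_conditional_logit <- function(cs, covars, name = "model") {
  fml <- stats::as.formula(paste("used ~", paste(covars, collapse = " + "),
                                 "+ strata(stratum_id) + cluster(animal_id)"))
  fit <- survival::clogit(fml, data = cs, method = "breslow")
  beta <- stats::coef(fit)
  if (any(!is.finite(beta))) {
    stop("singular design: ", paste(names(beta)[!is.finite(beta)],
                                    collapse = ", "), call. = FALSE)
  }
  if (any(abs(beta) > 15)) {
    warning("coefficient(s) at bound; possible complete separation: ",
            paste(names(beta)[abs(beta) > 15], collapse = ", "),
            call. = FALSE)
  }
  k <- length(beta)
  ll <- fit$loglik[2]
  structure(list(name = name, covars = covars, coef = beta,
                 se = sqrt(diag(fit$naive.var %||% fit$var)),
                 robust_se = sqrt(diag(fit$var)),
                 logLik = ll, k = k, AIC = -2 * ll + 2 * k,
                 n_strata = length(unique(cs$stratum_id)), fit = fit),
            class = "ssf_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a  # nolint

#' @export
print.ssf_fit <- function(x, ...) {
  cat(sprintf("<ssf_fit> %s: k = %d, logLik = %.2f, AIC = %.2f, strata = %d\n",
              x$name, x$k, x$logLik, x$AIC, x$n_strata))
  print(data.frame(coef = round(x$coef, 4), robust_se = round(x$robust_se, 4)))
  invisible(x)
}

#' The four candidate selection models
#'
#' Habitat only; habitat x status; habitat x release habitat; and habitat x
#' (status + release habitat). All retain step length; status and release-
#' habitat main effects are constant within strata and hence absorbed.
#'
#' @return Named list of covariate vectors.
#' @export
ssf_model_set <- function() {
  list(
    habitat            = c("hb", "hg", "sl_km"),
    habitat_x_status   = c("hb", "hg", "hb:tr", "hg:tr", "sl_km"),
    habitat_x_release  = c("hb", "hg", "hb:rh", "hg:rh", "sl_km"),
    habitat_x_status_release = c("hb", "hg", "hb:tr", "hg:tr",
                                 "hb:rh", "hg:rh", "sl_km"))
}

#' Fit and rank the candidate models by AIC
#'
#' Fits the four candidate models on identical strata, ranks them by AIC
#' with a 2-unit equivalence band, and (optionally) fits a post-hoc model
#' adding diel interactions to every habitat term of the top-ranked model.
#'
#' @param cs Covariate-prepared choice sets.
#' @param models Named list of covariate vectors (default [ssf_model_set()]).
#' @param diel_posthoc Add the diel-interaction post-hoc model?
#' @return List with `table` (name, k, logLik, AIC, dAIC, equivalent) and
#'   `fits`.
#' @export
rank_models_aic <- function(cs, models = ssf_model_set(),
                            diel_posthoc = TRUE) {
  fits <- lapply(names(models), function(nm) {
    fit_conditional_logit(cs, models[[nm]], nm)
  })
  names(fits) <- names(models)
  n_strata <- vapply(fits, function(f) f$n_strata, numeric(1))
  if (length(unique(n_strata)) != 1) {
    stop("models fitted on differing strata counts; comparison is unfair",
         call. = FALSE)
  }
  if (diel_posthoc) {
    top <- names(fits)[which.min(vapply(fits, function(f) f$AIC, numeric(1)))]
    base <- models[[top]]
    hab <- base[grepl("hb|hg", base)]
    ph <- unique(c(base, paste0(hab, ":noct")))
    fits[[paste0(top, "_x_diel")]] <-
      fit_conditional_logit(cs, ph, paste0(top, "_x_diel"))
  }
  tab <- data.frame(model = names(fits),
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  tab$equivalent <- tab$dAIC <= 2
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Weekly nocturnal selection coefficients for bottomland habitat
#'
#' For each group (status x release habitat), fits one conditional-logit
#' model to the group's nocturnal strata with a week-specific bottomland
#' coefficient (week as an interaction on the bottomland dummy), retaining
#' grassland and step length. Weeks without bottomland variation yield
#' missing values.
#'
#' @param cs Covariate-prepared choice sets.
#' @param n_weeks Number of release-relative weeks (13 over 90 days).
#' @return Data frame: `status`, `release_habitat`, `week`,
#'   `beta_bottomland`, `se` (cluster-robust), `n_strata`.
#' @export
weekly_selection_series <- function(cs, n_weeks = 13) {
  noct <- cs[cs$noct == 1L & cs$week <= n_weeks, ]
  groups <- unique(cs[c("status", "release_habitat")])
  out <- list()
  for (g in seq_len(nrow(groups))) {
    d <- noct[noct$status == groups$status[g] &
              noct$release_habitat == groups$release_habitat[g], ]
    res <- data.frame(status = groups$status[g],
                      release_habitat = groups$release_habitat[g],
                      week = seq_len(n_weeks), beta_bottomland = NA_real_,
                      se = NA_real_, n_strata = 0L,
                      stringsAsFactors = FALSE)
    if (nrow(d) > 0) {
      strata_week <- tapply(d$week, d$stratum_id, function(w) w[1])
      res$n_strata <- as.integer(
        table(factor(strata_week, levels = seq_len(n_weeks))))
      wk_cols <- character(0)
      for (w in seq_len(n_weeks)) {
        cn <- paste0("hb_w", w)
        d[[cn]] <- d$hb * as.integer(d$week == w)
        # identifiable only if bottomland availability varies that week
        if (stats::var(d[[cn]]) > 0) wk_cols <- c(wk_cols, cn)
      }
      if (length(wk_cols) > 0) {
        fit <- tryCatch(
          fit_conditional_logit(d, c(wk_cols, "hg", "sl_km"),
                                paste0("weekly_",
                                       groups$status[g], "_",
                                       groups$release_habitat[g])),
          error = function(e) NULL)
        if (!is.null(fit)) {
          for (cn in wk_cols) {
            w <- as.integer(sub("hb_w", "", cn))
            if (cn %in% names(fit$coef)) {
              res$beta_bottomland[w] <- fit$coef[[cn]]
              res$se[w] <- fit$robust_se[[which(names(fit$coef) == cn)]]
            }
          }
        }
      }
    }
    out[[g]] <- res
  }
  do.call(rbind, out)
}
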