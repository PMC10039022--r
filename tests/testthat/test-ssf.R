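test_that("diel classification: fixed clock window and solar position", {
  fixed <- ssf_config(diel_mode = "fixed")
  noon <- as.POSIXct("2015-06-21 12:00:00", tz = "UTC")
  midnight <- as.POSIXct("2015-06-21 00:00:00", tz = "UTC")
  expect_equal(classify_diel(noon, fixed), "diurnal")
  expect_equal(classify_diel(midnight, fixed), "nocturnal")
  # solar mode at the study latitude: midsummer daylength is 14-15 h
  solar <- ssf_config(diel_mode = "solar", site_latlon = c(33.3, -81.7))
  tt <- as.POSIXct("2015-06-21", tz = "UTC") + seq(0, 86340, by = 60)
  daylen_h <- sum(classify_diel(tt, solar) == "diurnal") / 60
  expect_gt(daylen_h, 14)
  expect_lt(daylen_h, 15)
  # independent almanac oracle
  expect_equal(daylen_h, geosphere::daylength(33.3, 172), tolerance = 0.02)
  # local small hours (07:00 UTC is about 01:30 true solar time here)
  expect_equal(classify_diel(as.POSIXct("2015-06-21 07:00:00", tz = "UTC"),
                             solar), "nocturnal")
  expect_error(ssf_config(diel_mode = "solar", site_latlon = c(NA, NA)),
               "site_latlon")
})

test_that("kernels pool residents, stratify translocated, exclude focal", {
  trs <- list(
    mk_traj(cumsum(runif(40, 50, 100)), rep(0, 40), id = "resA",
            release_habitat = "upland_pine"),
    mk_traj(cumsum(runif(40, 50, 100)), rep(1000, 40), id = "resB",
            release_habitat = "bottomland"),
    mk_traj(cumsum(runif(40, 50, 100)), rep(2000, 40), id = "trA",
            status = "translocated", release_habitat = "upland_pine",
            capture_xy = c(50000, 0)),
    mk_traj(cumsum(runif(40, 50, 100)), rep(3000, 40), id = "trB",
            status = "translocated", release_habitat = "upland_pine",
            capture_xy = c(50000, 0)))
  pa <- movephase:::truth_phases(30)  # day 29 exploration, day 30 on
  st <- build_step_table(trs, list(upland_pine = pa), ssf_config())
  expect_equal(phase_of_day(pa, 29), "exploration")
  expect_equal(phase_of_day(pa, 30), "exploitation")
  kern <- build_kernels(st)
  # residents pooled regardless of habitat
  expect_true("resident" %in% names(kern))
  expect_setequal(unique(kern$resident$animal_id), c("resA", "resB"))
  # the kernel applied to trA contains only trB's steps
  ks <- kernel_sample(kern, "translocated.upland_pine.exploration", "trA")
  n_trB <- sum(st$animal_id == "trB" & st$phase == "exploration" &
               !is.na(st$turning_angle))
  expect_equal(length(ks$length), n_trB)
  # exclusion is idempotent: re-excluding changes nothing
  expect_identical(ks,
                   kernel_sample(kern,
                                 "translocated.upland_pine.exploration",
                                 "trA"))
  expect_error(kernel_sample(kern, "no.such.kernel"), "no kernel")
})

test_that("random steps: degenerate kernel, determinism, large-n mean", {
  kern1 <- list(length = 100, angle = 0)
  rs <- generate_random_steps(0, 0, 0, kern1, 5)
  expect_equal(rs$x1, rep(100, 5))
  expect_equal(rs$y1, rep(0, 5))
  expect_error(generate_random_steps(0, 0, NA, kern1, 5), "heading")
  set.seed(33)
  kern <- list(length = runif(200, 10, 400),
               angle = runif(200, -pi, pi))
  set.seed(1); a <- generate_random_steps(0, 0, 0.3, kern, 50)
  set.seed(1); b <- generate_random_steps(0, 0, 0.3, kern, 50)
  expect_identical(a, b)
  set.seed(2)
  big <- generate_random_steps(0, 0, 0, kern, 1e4)
  se <- sd(kern$length) / sqrt(1e4)
  expect_lt(abs(mean(big$length) - mean(kern$length)), 2 * se * 1.5)
})

test_that("habitat annotation uses the half-open cell convention", {
  ls <- mk_halfplane(n = 10, cell = 30)  # bottomland x < 150, pine beyond
  expect_equal(class_at(ls, 15, 15), "bottomland")
  expect_equal(class_at(ls, 150, 15), "upland_pine")  # left edge inclusive
  expect_equal(class_at(ls, 149.999, 15), "bottomland")
  expect_true(is.na(class_at(ls, -1, 15)))
})

test_that("choice sets: cardinality, invalid-used drops, reproducibility", {
  set.seed(21)
  mk_walk <- function(id, y0) {
    mk_traj(1500 + cumsum(rnorm(60, 0, 80)), y0 + cumsum(rnorm(60, 0, 80)),
            id = id)
  }
  trs <- list(mk_walk("w1", 1400), mk_walk("w2", 1600))
  st <- build_step_table(trs, list(), ssf_config())
  kern <- build_kernels(st)
  ls <- mk_halfplane(n = 100, cell = 30)
  cs1 <- assemble_choice_sets(st, kern, ls, ssf_config(), seed = 5)
  cs2 <- assemble_choice_sets(st, kern, ls, ssf_config(), seed = 5)
  expect_identical(cs1, cs2)
  # full strata carry exactly 21 alternatives with exactly one used
  tab <- table(cs1$stratum_id)
  expect_true(all(tab <= 21))
  used_per <- tapply(cs1$used, cs1$stratum_id, sum)
  expect_true(all(used_per == 1))
  # strata whose used endpoint is off-raster / excluded are dropped
  ls_small <- mk_halfplane(n = 40, cell = 30)  # 1200 m: walks exit
  cs3 <- assemble_choice_sets(st, kern, ls_small, ssf_config(), seed = 5)
  off <- class_at(ls_small, st$x1, st$y1)
  dropped_expected <- sum(is.na(off[!is.na(st$prev_heading)]))
  expect_equal(unname(attr(cs3, "dropped")["used_invalid"]),
               dropped_expected)
})

test_that("conditional-logit likelihood matches direct enumeration", {
  d <- mk_toy_strata(3, 20, seed = 7)
  X <- as.matrix(d[c("x1", "x2")])
  # beta = 0: every 21-way stratum contributes -log(21)
  expect_equal(clogit_loglik(X, d$used, d$stratum_id, c(0, 0)),
               -3 * log(21))
  fit <- fit_conditional_logit(d, c("x1", "x2"))
  # enumeration oracle at the fitted coefficients
  expect_equal(clogit_loglik(X, d$used, d$stratum_id, fit$coef),
               fit$logLik, tolerance = 1e-10)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * 2)
  # likelihood is invariant to adding a within-stratum constant
  d2 <- d
  d2$x1 <- d$x1 + as.numeric(d$stratum_id) * 7
  expect_equal(clogit_loglik(as.matrix(d2[c("x1", "x2")]), d$used,
                             d$stratum_id, fit$coef),
               clogit_loglik(X, d$used, d$stratum_id, fit$coef),
               tolerance = 1e-8)
  f2 <- fit_conditional_logit(d2, c("x1", "x2"))
  expect_equal(f2$logLik, fit$logLik, tolerance = 1e-8)
  expect_equal(unname(f2$coef), unname(fit$coef), tolerance = 1e-6)
})

test_that("model set and AIC ranking behave on null data", {
  set.seed(12)
  n_s <- 120
  d <- do.call(rbind, lapply(seq_len(n_s), function(s) {
    data.frame(stratum_id = s, animal_id = paste0("a", s %% 5),
               status = ifelse(s %% 2 == 0, "resident", "translocated"),
               release_habitat = ifelse(s %% 4 < 2, "upland_pine",
                                        "bottomland"),
               diel = "nocturnal", week = (s %% 13) + 1, phase = "exploitation",
               used = c(1L, rep(0L, 20)),
               habitat = sample(c("bottomland", "upland_pine", "grassland"),
                                21, TRUE),
               length = runif(21, 10, 400), angle = runif(21, -pi, pi))
  }))
  d <- prepare_ssf_covariates(d)
  rk <- rank_models_aic(d, diel_posthoc = FALSE)
  expect_equal(nrow(rk$table), 4L)
  expect_true(all(diff(rk$table$AIC) >= 0))
  expect_true(rk$table$equivalent[1])
  # under no selection the simplest model should not lose badly
  expect_lt(rk$table$AIC[rk$table$model == "habitat"],
            min(rk$table$AIC) + 10)
})

test_that("weekly series: empty groups and missing weeks do not crash", {
  d <- mk_toy_strata(4, 20, seed = 3)
  d$status <- "translocated"; d$release_habitat <- "upland_pine"
  d$noct <- 0L  # no nocturnal strata at all
  d$week <- 1L; d$hb <- 0L; d$hg <- 0L; d$sl_km <- 0.1
  wk <- weekly_selection_series(d)
  expect_equal(nrow(wk), 13L)
  expect_true(all(is.na(wk$beta_bottomland)))
  expect_true(all(wk$n_strata == 0L))
})
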