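test_that("landscape generation hits class fractions with patches", {
  ls <- generate_landscape(7, width_m = 9000, height_m = 9000)
  fr <- table(factor(ls$values, levels = ls$legend,
                     labels = names(ls$legend))) / length(ls$values)
  expect_equal(unname(fr[["bottomland"]]), 0.26, tolerance = 0.03)
  expect_equal(unname(fr[["upland_pine"]]), 0.44, tolerance = 0.03)
  # seeded reproducibility
  expect_identical(ls$values,
                   generate_landscape(7, width_m = 9000,
                                      height_m = 9000)$values)
  # single-class degenerate case
  u <- generate_landscape(7, width_m = 3000, height_m = 3000,
                          class_fractions = c(upland_pine = 1))
  expect_true(all(u$values == u$legend[["upland_pine"]]))
  expect_error(generate_landscape(7, patch_scale = 40), "speckle")
})

test_that("ESRI ASCII grids round-trip exactly", {
  ls <- generate_landscape(8, width_m = 3000, height_m = 2400)
  f <- tempfile(fileext = ".asc")
  write_esri_ascii(ls, f)
  back <- read_esri_ascii(f)
  expect_identical(back$values, ls$values)
  expect_equal(back$origin, ls$origin)
  expect_equal(back$cell_size, ls$cell_size)
})

test_that("simulated agents honour kernels when selection is off", {
  ls <- mk_uniform(2L, n = 400, cell = 30)  # uniform pine, no habitat signal
  cfg <- sim_config(beta = list(exploration = c(bottomland = 0,
                                                grassland = 0),
                                exploitation = c(bottomland = 0,
                                                 grassland = 0)),
                    attraction_resident = 0, horizon_days = 90)
  tr <- simulate_agent(ls, cfg, "resident", c(6000, 6000),
                       animal_id = "ks", seed = 9)
  st <- compute_steps(trajectory(
    data.frame(t = tr$fixes$t, x = attr(tr, "true_xy")[, 1],
               y = attr(tr, "true_xy")[, 2]), tr$meta))
  set.seed(10)
  ref_len <- rgamma(1000, cfg$step_shape, scale = cfg$step_scale_exploit)
  ref_ang <- wrap_angle(rnorm(1000, 0, cfg$angle_sd_exploit))
  expect_gt(ks.test(st$length[1:1000], ref_len)$p.value, 0.01)
  expect_gt(ks.test(na.omit(st$turning_angle)[1:1000], ref_ang)$p.value,
            0.01)
})

test_that("telemetry noise has the configured scale", {
  ls <- mk_uniform(2L, n = 400, cell = 30)
  cfg <- sim_config(horizon_days = 90)
  tr <- simulate_agent(ls, cfg, "resident", c(6000, 6000),
                       animal_id = "tn", seed = 4)
  err <- cbind(tr$fixes$x - attr(tr, "true_xy")[, 1],
               tr$fixes$y - attr(tr, "true_xy")[, 2])
  expect_equal(sd(as.vector(err)), 15, tolerance = 0.1 * 15)
})

test_that("strong bottomland preference shows up as a selection ratio", {
  ratios <- vapply(1:5, function(s) {
    ls <- generate_landscape(child_seed(s, "ls"), width_m = 9000,
                             height_m = 9000)
    cfg <- sim_config(beta = list(
      exploration = c(bottomland = 2, grassland = 0),
      exploitation = c(bottomland = 2, grassland = 0)),
      attraction_resident = 0, horizon_days = 60)
    set.seed(s)
    start <- movephase:::sample_start(ls, "upland_pine", margin_m = 1500)
    tr <- simulate_agent(ls, cfg, "resident", start,
                         animal_id = "sr", seed = child_seed(s, "ag"))
    cls <- class_at(ls, tr$fixes$x, tr$fixes$y)
    frac_b <- table(factor(ls$values, levels = ls$legend,
                           labels = names(ls$legend)))[["bottomland"]] /
      length(ls$values)
    mean(cls == "bottomland", na.rm = TRUE) / frac_b
  }, numeric(1))
  expect_gt(median(ratios), 1.5)
})

test_that("cohorts carry counts, truth passthrough and determinism", {
  cfg <- sim_config(n_resident_upland = 1, n_resident_bottomland = 1,
                    n_translocated_upland = 1, n_translocated_bottomland = 1,
                    horizon_days = 6, homecoming_prob = 0)
  co <- simulate_cohort(cfg, seed = 2)
  expect_length(co$trajectories, 4L)
  expect_true(all(vapply(co$trajectories, n_fixes, integer(1)) == 6 * 12))
  expect_identical(co$truth$beta, cfg$beta)
  expect_equal(co$truth$switch_day, cfg$switch_day)
  co2 <- simulate_cohort(cfg, seed = 2)
  expect_identical(co$meta, co2$meta)
  expect_identical(lapply(co$trajectories, function(x) x$fixes),
                   lapply(co2$trajectories, function(x) x$fixes))
  # translocated animals are released >= the minimum distance from capture
  m <- co$meta[co$meta$status == "translocated", ]
  d <- sqrt((m$release_x - m$capture_x)^2 + (m$release_y - m$capture_y)^2)
  expect_true(all(d >= cfg$min_translocation_m))
  expect_error(simulate_agent(co$landscape, cfg, "resident", c(-1e6, 0)),
               "excluded")
})

test_that("written cohorts are read back by the pipeline's readers", {
  cfg <- sim_config(n_resident_upland = 1, n_resident_bottomland = 0,
                    n_translocated_upland = 1, n_translocated_bottomland = 0,
                    horizon_days = 4, homecoming_prob = 0)
  co <- simulate_cohort(cfg, seed = 3)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  trajs <- read_gps_csv(file.path(dir, "gps.csv"))
  metas <- read_animal_meta(file.path(dir, "meta.csv"))
  expect_setequal(names(trajs), names(co$trajectories))
  expect_equal(n_fixes(trajs[[1]]), 4 * 12)
  expect_equal(metas[[co$meta$animal_id[2]]]$status, co$meta$status[2])
  ls <- read_esri_ascii(file.path(dir, "landcover.asc"))
  expect_identical(ls$values, co$landscape$values)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$switch_day, cfg$switch_day)
})

test_that("homecoming agents reach the capture range inside the window", {
  ls <- generate_landscape(5)
  cfg <- sim_config(horizon_days = 20)
  set.seed(14)
  cap <- movephase:::sample_start(ls, "bottomland")
  repeat {
    rel <- movephase:::sample_start(ls, "upland_pine")
    if (sqrt(sum((cap - rel)^2)) >= cfg$min_translocation_m) break
  }
  tr <- simulate_agent(ls, cfg, "homecomer", rel, cap, "hc", seed = 6)
  ht <- detect_homing_return(tr)
  expect_false(is.null(ht))
  out <- apply_censoring(tr, ht)
  expect_equal(out$meta$status, "resident")
})
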