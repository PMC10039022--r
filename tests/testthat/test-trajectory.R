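test_that("read_gps_csv splits, sorts and deduplicates animals", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(
    animal_id = c("b", "a", "a", "b", "a", "a"),
    timestamp = c("2015-01-01T04:00:00", "2015-01-01T02:00:00",
                  "2015-01-01T00:00:00", "2015-01-01T00:00:00",
                  "2015-01-01T04:00:00", "2015-01-01T04:00:00"),
    x = 1:6, y = 1:6, pdop = 2)
  write.csv(df, f, row.names = FALSE)
  expect_warning(trajs <- read_gps_csv(f), "duplicate")
  expect_named(trajs, c("a", "b"))
  # duplicate (a, 04:00) collapsed to first occurrence
  expect_equal(sum(vapply(trajs, n_fixes, integer(1))), 5L)
  expect_true(all(diff(trajs$a$fixes$t) > 0))
  expect_equal(trajs$a$fixes$x, c(3, 2, 5))  # time-sorted
})

test_that("read_gps_csv reports configuration and row-level errors", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = "a", timestamp = "2015-01-01", x = 1, y = 1),
            f, row.names = FALSE)
  expect_error(read_gps_csv(f), "missing required column")
  write.csv(data.frame(animal_id = "a", timestamp = "not-a-time",
                       x = 1, y = 1), f, row.names = FALSE)
  expect_error(read_gps_csv(f), "line")
})

test_that("PDOP filter is strict (> max removed), keeps missing values", {
  tr <- mk_traj(1:4, 1:4, pdop = c(3, 9, 9.1, NA))
  out <- filter_pdop(tr)
  expect_equal(out$fixes$pdop, c(3, 9, NA))
  expect_identical(filter_pdop(out)$fixes, out$fixes)  # idempotent
  expect_identical(filter_pdop(mk_traj(1:3, 1:3, pdop = c(1, 5, 9)))$fixes,
                   mk_traj(1:3, 1:3, pdop = c(1, 5, 9))$fixes)
  expect_warning(empty <- filter_pdop(mk_traj(1:3, 1:3, pdop = 20)),
                 "all fixes removed")
  expect_equal(n_fixes(empty), 0L)
})

test_that("interval subsampling thins fine schedules to 2 h", {
  # 15-min fixes over 24 h: 97 fixes -> 13 at 2-h cadence
  tr15 <- mk_traj(1:97, 1:97, dt = 900)
  out <- resample_to_interval(tr15)
  expect_equal(n_fixes(out), 13L)
  expect_true(all(diff(as.numeric(out$fixes$t)) == 7200))
  # oracle: brute-force greedy walk over the same fixture
  tt <- as.numeric(tr15$fixes$t)
  keep <- 1
  repeat {
    tgt <- tt[keep[length(keep)]] + 7200
    cand <- which(abs(tt - tgt) <= 900 & seq_along(tt) > keep[length(keep)])
    if (length(cand) == 0) break
    keep <- c(keep, cand[which.min(abs(tt[cand] - tgt))])
  }
  expect_equal(out$fixes$x, tr15$fixes$x[keep])
})

test_that("subsampling is idempotent and never interpolates across gaps", {
  tr2h <- mk_traj(1:10, 1:10, dt = 7200)
  expect_identical(resample_to_interval(tr2h)$fixes, tr2h$fixes)
  # a 6-h gap: next kept fix is the first after the gap; nothing fabricated
  t <- t_origin + c(0, 2, 4, 10, 12) * 3600
  tr <- mk_traj(1:5, 1:5, t = t)
  out <- resample_to_interval(tr)
  expect_equal(out$fixes$x, c(1, 2, 3, 4, 5))
  expect_true(all(out$fixes$t %in% tr$fixes$t))
})

test_that("step geometry: lengths, headings, turning angles", {
  tr <- mk_traj(c(0, 3, 3), c(0, 4, 9))
  st <- compute_steps(tr)
  expect_equal(nrow(st), 2L)
  expect_equal(st$length, c(5, 5))
  expect_true(is.na(st$turning_angle[1]))
  # left turn from heading atan2(4,3) to pi/2
  expect_equal(st$turning_angle[2], pi / 2 - atan2(4, 3), tolerance = 1e-12)
  expect_equal(st$turning_angle[2], 0.6435011, tolerance = 1e-6)
  # collinear eastward track: all defined turning angles are zero
  st2 <- compute_steps(mk_traj(0:5, rep(0, 6)))
  expect_equal(st2$turning_angle[-1], rep(0, 4))
  # zero-displacement step: its heading and the next turning angle undefined
  st3 <- compute_steps(mk_traj(c(0, 1, 1, 2), c(0, 0, 0, 0)))
  expect_true(is.na(st3$heading[2]))
  expect_true(is.na(st3$turning_angle[3]))
  expect_equal(nrow(compute_steps(mk_traj(1, 1))), 0L)
})

test_that("homing returns are detected only within the 10-day window", {
  # returner: starts 10 km out, inside 1.5 km of capture on day 6
  n <- 12 * 20
  d <- seq(10000, 0, length.out = 12 * 6)
  x <- c(d, rep(0, n - length(d)))
  tr <- mk_traj(x, rep(0, n), status = "translocated",
                release_xy = c(10000, 0), capture_xy = c(0, 0))
  ht <- detect_homing_return(tr)
  expect_equal(ht, tr$fixes$t[which(x <= 1600)[1]])
  # scan oracle: first fix within radius
  expect_equal(ht, min(tr$fixes$t[sqrt(x^2) <= 1600]))
  # never close: nothing detected
  far <- mk_traj(seq(20000, 15000, length.out = 50), rep(0, 50),
                 status = "translocated", release_xy = c(20000, 0),
                 capture_xy = c(0, 0))
  expect_null(detect_homing_return(far))
  # entry on day 40 is outside the homing window
  x2 <- c(rep(10000, 12 * 39), rep(0, 12 * 3))
  late <- mk_traj(x2, rep(0, length(x2)), status = "translocated",
                  release_xy = c(10000, 0), capture_xy = c(0, 0))
  expect_null(detect_homing_return(late))
  expect_error(detect_homing_return(mk_traj(1:3, 1:3)), "translocated")
})

test_that("censoring: homing reclassifies, windows drop fixes, 90-day cut", {
  n <- 12 * 20
  d <- seq(10000, 0, length.out = 12 * 6)
  x <- c(d, rep(0, n - length(d)))
  tr <- mk_traj(x, rep(0, n), status = "translocated",
                release_xy = c(10000, 0), capture_xy = c(0, 0))
  tr$meta$capture_habitat <- "bottomland"
  ht <- detect_homing_return(tr)
  out <- apply_censoring(tr, ht)
  expect_equal(out$meta$status, "resident")
  expect_equal(out$meta$release_xy, c(0, 0))
  expect_equal(out$meta$release_habitat, "bottomland")
  expect_true(all(out$fixes$t >= ht))
  # no censoring and no homing: identity up to the 90-day horizon
  long <- mk_traj(seq_len(12 * 209), rep(0, 12 * 209))
  cut <- apply_censoring(long, NULL)
  expect_true(max(as.numeric(cut$fixes$t) - as.numeric(cut$fixes$t[1])) <
              90 * 86400)
  expect_identical(apply_censoring(mk_traj(1:5, 1:5), NULL)$fixes,
                   mk_traj(1:5, 1:5)$fixes)
  # analyst-supplied censor window removes its fixes
  cw <- data.frame(start = t_origin + 3600 * 4, end = t_origin + 3600 * 8)
  tr2 <- mk_traj(1:10, 1:10)
  tr2$meta$censor_windows <- cw
  out2 <- apply_censoring(tr2, NULL)
  expect_false(any(out2$fixes$t >= cw$start & out2$fixes$t <= cw$end))
})

test_that("preprocessing never fabricates fixes and keeps step counts", {
  set.seed(5)
  tr <- mk_traj(cumsum(rnorm(300, 0, 100)), cumsum(rnorm(300, 0, 100)),
                dt = 3600, pdop = sample(c(2, 3, 12), 300, TRUE))
  out <- preprocess_trajectory(tr)
  key_in <- paste(tr$fixes$t, tr$fixes$x)
  key_out <- paste(out$fixes$t, out$fixes$x)
  expect_true(all(key_out %in% key_in))
  expect_equal(nrow(compute_steps(out)), n_fixes(out) - 1L)
})
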