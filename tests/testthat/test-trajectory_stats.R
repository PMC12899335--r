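test_that("finite-difference kinematics recover polynomial derivatives", {
  dt <- 0.1
  t <- seq(0, 5, by = dt)
  # x = 3t (v = 3), y = t^2 (a = 2), z constant
  rec <- trajectory_record(cbind(3 * t, t^2, 7), FALSE, dt = dt)
  k <- kinematics(rec)
  interior <- 2:(length(t) - 1)
  expect_equal(k$velocity[interior, 1], rep(3, length(interior)),
               tolerance = 1e-9)
  expect_equal(k$velocity[interior, 2], 2 * t[interior], tolerance = 1e-9)
  expect_equal(k$acceleration[interior, 2], rep(2, length(interior)),
               tolerance = 1e-9)
  expect_equal(k$acceleration[interior, 3], rep(0, length(interior)),
               tolerance = 1e-9)
})

test_that("curvature of a sampled circle is 1/R and scales as expected", {
  for (R in c(5, 20)) {
    th <- seq(0, 2 * pi, length.out = 400)
    rec <- trajectory_record(cbind(R * cos(th), R * sin(th), 10), FALSE,
                             dt = 0.05)
    kap <- curvature_series(rec)
    interior <- 3:(length(th) - 2)
    expect_equal(stats::median(kap[interior]), 1 / R, tolerance = 1e-3)
  }
  # a straight line has zero curvature
  line <- trajectory_record(cbind(seq(0, 10, 0.1), 0, 0), FALSE, dt = 0.1)
  expect_lt(max(curvature_series(line), na.rm = TRUE), 1e-9)
})

test_that("velocity autocorrelation is 1 at lag zero and decays for noise", {
  set.seed(6)
  # random-walk positions -> white-noise velocity -> near-zero correlation
  pos <- apply(matrix(rnorm(3000), ncol = 3), 2, cumsum)
  rec <- trajectory_record(pos, FALSE, dt = 0.03)
  rho <- velocity_autocorrelation(rec, max_lag = 10)
  expect_equal(rho[1], 1)
  expect_false(attr(rho, "degenerate"))
  # central differencing induces rho(1) ~ 0.5; from lag 3 on, white noise
  expect_true(all(abs(rho[4:11]) < 3 / sqrt(1000)))

  # constant-velocity motion is degenerate
  lin <- trajectory_record(cbind(1:100, 0, 0), FALSE, dt = 0.1)
  rho2 <- velocity_autocorrelation(lin, max_lag = 5)
  expect_true(attr(rho2, "degenerate"))
  expect_true(all(is.na(rho2[-1])))

  # smooth circular motion stays strongly correlated at short lags
  th <- seq(0, 2 * pi, length.out = 500)
  circ <- trajectory_record(cbind(20 * cos(th), 20 * sin(th), 0), FALSE,
                            dt = 0.05)
  rho3 <- velocity_autocorrelation(circ, max_lag = 5)
  expect_true(all(rho3 > 0.9))
})

test_that("altitude-change histogram counts every step exactly once", {
  rec <- trajectory_record(cbind(0, 0, c(0, 1, 1, 3, 2, 2.5)), FALSE)
  h <- altitude_change_hist(rec, n_bins = 4)
  expect_equal(sum(h$counts), 5)
  expect_length(h$edges, 5)
  expect_equal(h$edges[1], -1)  # min dz
  expect_equal(h$edges[5], 2)   # max dz
  # constant altitude: degenerate range handled
  flat <- trajectory_record(cbind(1:5, 0, 10), FALSE)
  hf <- altitude_change_hist(flat, n_bins = 3)
  expect_equal(sum(hf$counts), 4)
})

test_that("simulated birds pass their own plausibility audit", {
  for (preset in c("pigeon", "gull", "peregrine")) {
    rec <- simulate_trajectory("bird", preset, horizon = 60,
                               seed = match(preset, c("pigeon", "gull",
                                                      "peregrine")))
    rep <- plausibility_report(rec, species_preset(preset))
    expect_equal(nrow(rep$violations), 0,
                 label = sprintf("%s violations", preset))
    expect_true(rep$speed_range_ok)
    expect_true(rep$continuity_ok)
    expect_lte(rep$max_lateral_accel,
               rep$lateral_accel_bound * 1.05 +
                 rep$lateral_accel_allowance)
  }
})

test_that("the plausibility audit flags physically impossible motion", {
  rec <- simulate_trajectory("bird", "pigeon", horizon = 30, seed = 2)
  sp <- species_preset("pigeon")

  # teleport: a 50 m jump in one 0.03 s step
  pos <- rec$positions
  pos[500:nrow(pos), 1] <- pos[500:nrow(pos), 1] + 50
  bad <- trajectory_record(pos, FALSE, species = "pigeon", dt = rec$dt)
  repb <- plausibility_report(bad, sp)
  expect_false(repb$continuity_ok)
  expect_true("continuity" %in% repb$violations$rule)

  # a turn far tighter than the bank limit permits: circle of radius 5 m
  # at 12 m/s needs 28.8 m/s^2 of lateral acceleration >> g tan(40 deg)
  th <- seq(0, 10 * pi, length.out = 2001)
  tight <- trajectory_record(cbind(5 * cos(th), 5 * sin(th), 40), FALSE,
                             dt = 5 * 10 * pi / (2000 * 12))
  rept <- plausibility_report(tight, sp)
  expect_true("lateral_acceleration" %in% rept$violations$rule)

  # drone records are rejected outright
  drone <- simulate_trajectory("drone", horizon = 10, seed = 2)
  expect_error(plausibility_report(drone, sp), "bird")
})

test_that("diversity report measures pairwise RMS displacement", {
  rec <- simulate_trajectory("bird", "gull", horizon = 10, seed = 5)
  shifted <- rec
  shifted$positions <- rec$positions + matrix(c(60, 80, 0),
                                              nrow(rec$positions), 3,
                                              byrow = TRUE)
  div <- diversity_report(list(rec, shifted))
  expect_equal(div$rms[1, 2], 100, tolerance = 1e-9) # 3-4-5 triangle
  expect_equal(nrow(div$flagged), 0)

  # exact duplicates are flagged
  div2 <- diversity_report(list(rec, rec))
  expect_equal(div2$rms[1, 2], 0)
  expect_equal(nrow(div2$flagged), 1)
  expect_error(diversity_report(list(rec)), "two records")
})

test_that("gust model injects velocity variance; calm air injects none", {
  v <- gust_velocity_variance("bird", "pigeon", seed = 4, horizon = 20)
  expect_length(v, 3)
  expect_true(all(v > 0))
})

test_that("trajectory_summary and validate_dataset aggregate the statistics", {
  rec <- simulate_trajectory("bird", "pigeon", horizon = 10, seed = 6)
  s <- trajectory_summary(rec)
  expect_s3_class(s, "trajectory_summary")
  expect_equal(length(s$speed), nrow(rec$positions))
  expect_equal(s$velocity_acf[1], 1)
  expect_length(s$position_variance, 3)

  dir <- file.path(tempdir(), "ds-validate")
  unlink(dir, recursive = TRUE)
  generate_dataset(2, dir, seed = 9, horizon = 10)
  csv <- tempfile(fileext = ".csv")
  df <- validate_dataset(dir, report = csv)
  expect_equal(nrow(df), 4)
  expect_true(all(df$violations[!df$is_drone] == 0))
  expect_true(file.exists(csv))
})
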