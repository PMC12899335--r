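test_that("closed-form turn radius and yaw rate satisfy the banked-turn relations", {
  # tan(45 deg) = 1, so at V = sqrt(g * R): R = V^2 / g
  expect_equal(turn_radius(45 * pi / 180, sqrt(GRAVITY * 10)), 10,
               tolerance = 1e-12)
  expect_equal(turn_radius(60 * pi / 180, 10),
               100 / (GRAVITY * tan(pi / 3)), tolerance = 1e-12)
  expect_equal(yaw_rate(60 * pi / 180, 10), GRAVITY * tan(pi / 3) / 10,
               tolerance = 1e-12)
  # identity: yaw_rate * turn_radius = V, for a grid of (phi, V)
  for (phi in c(0.1, 0.5, 1.0, 1.4)) {
    for (V in c(2, 10, 30)) {
      expect_equal(yaw_rate(phi, V) * turn_radius(phi, V), V,
                   tolerance = 1e-12)
    }
  }
  expect_error(turn_radius(0, 10), "phi")
  expect_error(turn_radius(pi / 2, 10), "phi")
  expect_error(turn_radius(0.5, -1), "V")
  expect_error(yaw_rate(-0.1, 10), "phi")
})

test_that("Rodrigues rotation matches known rotations and preserves norms", {
  expect_equal(rodrigues_rotate(c(1, 0, 0), c(0, 0, 1), pi / 2),
               c(0, 1, 0), tolerance = 1e-12)
  expect_equal(rodrigues_rotate(c(1, 0, 0), c(0, 0, 1), pi / 3),
               c(0.5, sqrt(3) / 2, 0), tolerance = 1e-12)
  expect_equal(rodrigues_rotate(c(0.3, -0.4, 0.5), c(0, 1, 0), 2 * pi),
               c(0.3, -0.4, 0.5), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(3)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    r <- rodrigues_rotate(v, ax, runif(1, -10, 10))
    expect_equal(sqrt(sum(r^2)), sqrt(sum(v^2)), tolerance = 1e-12)
  }
})

test_that("species presets validate and expose contrasting signatures", {
  p <- species_preset("pigeon"); g <- species_preset("gull")
  f <- species_preset("peregrine")
  expect_equal(p$s_star, 12)
  expect_gt(f$s_star, p$s_star)
  expect_gt(p$s_star, g$s_star)
  expect_gt(f$phi_max, p$phi_max)
  expect_error(species_preset("sparrow"))
  expect_error(species_params("x", k_s = -1, s_star = 10, beta_tw = 0.2,
                              sigma_s = 0.5, k_phi = 4, k_g = 1, k_h = 0.02,
                              k_w = 1, k_a = 3, phi_max = 0.7,
                              sigma_phi = 0.1, sigma_a = 0.5,
                              sigma_u = 0.08))
  expect_error(species_params("x", k_s = 1, s_star = 10, beta_tw = 0.2,
                              sigma_s = 0.5, k_phi = 4, k_g = 1, k_h = 0.02,
                              k_w = 1, k_a = 3, phi_max = pi / 2,
                              sigma_phi = 0.1, sigma_a = 0.5,
                              sigma_u = 0.08),
               "phi_max")
})

test_that("behavioural acceleration terms match their closed forms", {
  sp0 <- constant_bank_species()
  env <- still_environment(goal = c(0, 1e6, 40), h_pref = 40)

  # altitude hold only: a = k_h * (h_pref - z) * e_z
  sp <- sp0; sp$k_h <- 0.02
  b <- bird_state(x = c(0, 0, 30), u = c(1, 0, 0), s = 10)
  expect_equal(bird_behavioral_accel(b, sp, env, noise = FALSE),
               c(0, 0, 0.02 * 10), tolerance = 1e-12)

  # goal attraction only, goal perpendicular to the heading:
  # a = k_g * s * P_perp(goal_dir) = k_g * s * (0, 1, 0)
  sp <- sp0; sp$k_g <- 1.5
  b <- bird_state(x = c(0, 0, 40), u = c(1, 0, 0), s = 10)
  expect_equal(bird_behavioral_accel(b, sp, env, noise = FALSE),
               c(0, 1.5 * 10, 0), tolerance = 1e-9)

  # cross-wind compensation only: a = -k_w * P_perp(w_horizontal)
  sp <- sp0; sp$k_w <- 0.8
  envw <- environment_state(wind_config(w_base = c(0, 2, 0),
                                        sigma_gust = 0,
                                        thermal_strength = 0),
                            goal = c(1e6, 0, 40), h_pref = 40)
  expect_equal(bird_behavioral_accel(b, sp, envw, noise = FALSE),
               c(0, -0.8 * 2, 0), tolerance = 1e-12)

  # obstacle repulsion: k_a * (x - x_o) / d^3 within the cutoff
  sp <- sp0; sp$k_a <- 3
  envo <- still_environment(goal = c(1e6, 0, 40),
                            obstacles = matrix(c(0, 5, 40), 1))
  expect_equal(bird_behavioral_accel(b, sp, envo, noise = FALSE),
               c(0, -3 / 25, 0), tolerance = 1e-12)
  # beyond the cutoff the obstacle is ignored
  envf <- still_environment(goal = c(1e6, 0, 40),
                            obstacles = matrix(c(0, 40, 40), 1))
  expect_equal(bird_behavioral_accel(b, sp, envf, noise = FALSE),
               c(0, 0, 0), tolerance = 1e-12)
})

test_that("desired bank is signed by turn direction and saturated", {
  u <- c(1, 0, 0)
  # lateral command of magnitude g to the left (+y) -> +45 degrees
  expect_equal(desired_bank(c(0, GRAVITY, 0), u, pi / 3), pi / 4,
               tolerance = 1e-12)
  # to the right -> -45 degrees
  expect_equal(desired_bank(c(0, -GRAVITY, 0), u, pi / 3), -pi / 4,
               tolerance = 1e-12)
  # saturation at phi_max
  expect_equal(desired_bank(c(0, 100 * GRAVITY, 0), u, 40 * pi / 180),
               40 * pi / 180, tolerance = 1e-12)
  # aligned command produces no bank
  expect_equal(desired_bank(c(5, 0, 0), u, pi / 3), 0, tolerance = 1e-12)
  expect_equal(desired_bank(c(0, 0, 0), u, pi / 3), 0)
})

test_that("gain-free level flight is an equilibrium of bird_step", {
  sp <- constant_bank_species(s_star = 10)
  env <- still_environment()
  b <- bird_state(x = c(0, 0, 40), u = c(1, 0, 0), s = 10, phi = 0)
  set.seed(1)
  b2 <- bird_step(b, sp, env, 0.03)
  expect_equal(b2$u, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(b2$s, 10, tolerance = 1e-12)
  expect_equal(b2$phi, 0, tolerance = 1e-12)
  expect_equal(b2$x, c(0.3, 0, 40), tolerance = 1e-12)
})

test_that("tailwind coupling shifts the airspeed relaxation target", {
  # at s = s_star with tailwind w aligned to u: ds = k_s * beta_tw * w * dt
  sp <- constant_bank_species(s_star = 10)
  sp$k_s <- 1; sp$beta_tw <- 0.3
  env <- environment_state(wind_config(w_base = c(2, 0, 0), sigma_gust = 0,
                                       thermal_strength = 0),
                           goal = c(1e6, 0, 40), h_pref = 40)
  b <- bird_state(x = c(0, 0, 40), u = c(1, 0, 0), s = 10, phi = 0)
  dt <- 0.03
  set.seed(1)
  b2 <- bird_step(b, sp, env, dt)
  expect_equal(b2$s, 10 + 1 * 0.3 * 2 * dt, tolerance = 1e-12)
  # position advances by the updated airspeed plus wind (semi-implicit)
  expect_equal(b2$x[1], 0 + (b2$s + 2) * dt, tolerance = 1e-12)
})

test_that("constant-bank flight reproduces the coordinated-turn closed forms", {
  V <- 10; phi <- pi / 4; dt <- 0.01
  period <- 2 * pi / yaw_rate(phi, V)
  sim <- simulate_constant_bank(phi, V, dt, round(period / dt))
  r_meas <- measured_circle_radius(sim$positions[-1, , drop = FALSE])
  expect_equal(r_meas, turn_radius(phi, V), tolerance = 0.02)
  # altitude is untouched by a pure bank
  expect_equal(max(abs(sim$positions[, 3] - 40)), 0, tolerance = 1e-9)
  # heading returns to the start after one full period
  expect_equal(sim$u, c(1, 0, 0), tolerance = 0.02)
})

test_that("negative bank turns the opposite way", {
  V <- 10; dt <- 0.01
  left <- simulate_constant_bank(pi / 6, V, dt, 100)
  right <- simulate_constant_bank(-pi / 6, V, dt, 100)
  expect_gt(left$positions[101, 2], 0)   # positive bank curves toward +y
  expect_lt(right$positions[101, 2], 0)  # negative bank toward -y
  expect_equal(left$positions[, 2], -right$positions[, 2],
               tolerance = 1e-12)
})

test_that("stochastic flight respects the state invariants", {
  sp <- species_preset("pigeon")
  env <- environment_state()
  b <- bird_state(x = c(0, 0, 40), u = c(1, 0, 0), s = sp$s_star, phi = 0)
  set.seed(11)
  sim <- skyclass:::cpp_simulate_bird(unclass(b), unclass(sp), unclass(env),
                                      env$wind, env$gust, 5000, 0.03)
  expect_true(all(sim$speed >= sp$s_min - 1e-12))
  expect_true(all(sim$speed <= sp$s_max + 1e-12))
  expect_true(all(abs(sim$phi) <= sp$phi_max + 1e-12))
  expect_lt(abs(sqrt(sum(sim$u^2)) - 1), 1e-9)
  expect_true(all(is.finite(sim$positions)))
})

test_that("the peregrine preset flies faster than the pigeon preset", {
  mean_speed <- function(preset, seed) {
    rec <- simulate_trajectory("bird", preset, horizon = 30, seed = seed)
    sp <- attr(rec, "speed")
    mean(sp)
  }
  per <- vapply(1:8, function(s) mean_speed("peregrine", s), numeric(1))
  pig <- vapply(1:8, function(s) mean_speed("pigeon", s), numeric(1))
  expect_gt(mean(per), mean(pig))
})

test_that("hover is an equilibrium of the drone controller", {
  dp <- drone_params(sigma_ctrl = 0, sigma_yaw = 0, h_star = 30)
  env <- still_environment(goal = c(0, 0, 30), h_pref = 30)
  d <- drone_state(x = c(0, 0, 30), v = c(0, 0, 0))
  set.seed(1)
  d2 <- drone_step(d, dp, env, 0.03)
  expect_equal(d2$x, c(0, 0, 30), tolerance = 1e-9)
  expect_equal(d2$v, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(d2$t_hat, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(attr(d2, "tilt"), 0, tolerance = 1e-12)
  expect_equal(attr(d2, "thrust"), dp$mass * GRAVITY, tolerance = 1e-9)
})

test_that("the drone respects tilt, tilt-rate, thrust and ground limits", {
  dp <- drone_params(sigma_ctrl = 0, sigma_yaw = 0, h_star = 30)
  env <- still_environment(goal = c(500, 0, 30), h_pref = 30)
  d <- drone_state(x = c(0, 0, 30))
  dt <- 0.03
  set.seed(1)
  d2 <- drone_step(d, dp, env, dt)
  # rate limit: a single step cannot tilt further than tilt_rate_max * dt
  expect_lte(attr(d2, "tilt"), dp$tilt_rate_max * dt + 1e-12)
  expect_gt(attr(d2, "tilt"), 0)

  # over a long aggressive run: tilt <= tilt_max, 0 <= T <= thrust_max, z >= 0
  rec <- simulate_trajectory("drone", horizon = 60, seed = 3)
  thr <- attr(rec, "thrust")[-1] # entry 1 predates the first control step
  expect_true(all(attr(rec, "tilt") <= drone_params()$tilt_max + 1e-9))
  expect_true(all(thr >= 0))
  expect_true(all(thr <= drone_params()$thrust_max + 1e-9))
  expect_true(all(rec$positions[, 3] >= 0))
})

test_that("the drone converges to its waypoint in still air", {
  dp <- drone_params(sigma_ctrl = 0, sigma_yaw = 0, h_star = 30)
  env <- still_environment(goal = c(20, -10, 30), h_pref = 30)
  d0 <- drone_state(x = c(0, 0, 0))
  set.seed(1)
  sim <- skyclass:::cpp_simulate_drone(unclass(d0), unclass(dp),
                                       unclass(env), env$wind, env$gust,
                                       2000, 0.03)
  final <- sim$positions[nrow(sim$positions), ]
  expect_lt(sqrt(sum((final - c(20, -10, 30))^2)), 1)
})

test_that("state constructors validate their inputs", {
  expect_error(bird_state(u = c(0, 0, 0)), "heading")
  expect_error(bird_state(s = -1), "airspeed")
  expect_error(drone_state(x = c(0, 0, -1)), "altitude")
  expect_error(drone_params(mass = -1))
  expect_error(drone_params(tilt_max = pi / 2), "tilt_max")
  expect_error(bird_step(bird_state(), species_preset("gull"),
                         environment_state(), dt = 0), "dt")
})
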