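# Shared deterministic fixtures for the test suite.

# A species with every gain and noise amplitude switched off, so a bird holds
# its initial bank and airspeed exactly: the constant-bank coordinated-turn
# oracle of the closed forms turn_radius() / yaw_rate().
constant_bank_species <- function(s_star = 10, phi_max = 50 * pi / 180) {
  species_params("oracle", k_s = 0, s_star = s_star, beta_tw = 0,
                 sigma_s = 0, k_phi = 0, k_g = 0, k_h = 0, k_w = 0, k_a = 0,
                 phi_max = phi_max, sigma_phi = 0, sigma_a = 0, sigma_u = 0)
}

# Still air: no base wind, no gusts, no thermal.
still_environment <- function(goal = c(1e6, 0, 40), h_pref = 40,
                              obstacles = NULL) {
  environment_state(wind_config(w_base = c(0, 0, 0), sigma_gust = 0,
                                thermal_strength = 0),
                    goal = goal, h_pref = h_pref, obstacles = obstacles)
}

# Simulate a bird with all behavioural gains and noises zero, starting at a
# fixed bank angle: returns the matrix of positions of a coordinated turn.
simulate_constant_bank <- function(phi, V, dt, n_steps) {
  sp <- constant_bank_species(s_star = V)
  env <- still_environment()
  b <- bird_state(x = c(0, 0, 40), u = c(1, 0, 0), s = V, phi = phi)
  sim <- skyclass:::cpp_simulate_bird(unclass(b), unclass(sp), unclass(env),
                                      env$wind, env$gust, n_steps, dt)
  sim
}

# Radius of a closed horizontal path measured as the mean distance from the
# centroid of exactly one full period (unbiased for a circle).
measured_circle_radius <- function(positions) {
  cen <- colMeans(positions[, 1:2, drop = FALSE])
  mean(sqrt((positions[, 1] - cen[1])^2 + (positions[, 2] - cen[2])^2))
}

# Small, fast training problem shared by the training unit tests.
tiny_training_records <- function(n_per_class = 8, seed = 99) {
  dir <- file.path(tempdir(), sprintf("skyclass-tiny-%d-%d",
                                      n_per_class, seed))
  if (!dir.exists(dir))
    generate_dataset(n_per_class, dir, seed = seed, horizon = 30)
  load_dataset(dir)
}

tiny_config <- function(cell = "lstm", epochs = 3, seed = 5) {
  classifier_config(hidden = 8, dropout = 0.2, max_len = 30,
                    epochs = epochs, batch_size = 8, seed = seed,
                    cell = cell)
}
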