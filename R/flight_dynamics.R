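#' Species parameter set
#'
#' Parameters defining one bird species' flight signature in the kinematic
#' stochastic model: speed relaxation, bank-angle control, behavioural gains
#' and noise amplitudes. Noise amplitudes are Euler-Maruyama amplitudes
#' (scaled by `sqrt(dt)` per step).
#'
#' @param name Species label.
#' @param k_s Speed adaptation rate (1/s).
#' @param s_star Preferred airspeed (m/s).
#' @param beta_tw Tailwind sensitivity (dimensionless).
#' @param sigma_s Speed noise amplitude (m s^-1 s^-1/2).
#' @param k_phi Roll response rate (1/s).
#' @param k_g Goal-seeking strength (1/s; multiplies airspeed).
#' @param k_h Altitude control strength (m s^-2 per metre of error).
#' @param k_w Cross-wind compensation strength (1/s).
#' @param k_a Obstacle avoidance strength (m^3 s^-2).
#' @param phi_max Maximum bank angle (rad), in (0, pi/2).
#' @param sigma_phi Roll noise amplitude (rad s^-1/2).
#' @param sigma_a Lateral acceleration noise amplitude (m s^-2).
#' @param sigma_u Heading direction noise amplitude (s^-1/2).
#' @param s_min,s_max Plausible airspeed bounds (m/s); default half / 1.6
#'   times the cruise speed.
#' @param avoid_cutoff Obstacle repulsion cutoff distance (m).
#'
#' @return An object of class `species_params`.
#' @seealso [species_preset()] for the pigeon, gull and peregrine presets.
#' @export
species_params <- function(name, k_s, s_star, beta_tw, sigma_s, k_phi, k_g,
                           k_h, k_w, k_a, phi_max, sigma_phi, sigma_a,
                           sigma_u, s_min = 0.5 * s_star,
                           s_max = 1.6 * s_star, avoid_cutoff = 25) {
  vals <- c(k_s = k_s, beta_tw = beta_tw, sigma_s = sigma_s, k_phi = k_phi,
            k_g = k_g, k_h = k_h, k_w = k_w, k_a = k_a,
            sigma_phi = sigma_phi, sigma_a = sigma_a, sigma_u = sigma_u)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rates and noise amplitudes must be finite and non-negative")
  if (!is.finite(phi_max) || phi_max <= 0 || phi_max >= pi / 2)
    stop("phi_max must lie in (0, pi/2)")
  if (!(s_min < s_star && s_star < s_max))
    stop("speed bounds must satisfy s_min < s_star < s_max")
  structure(list(name = name, k_s = k_s, s_star = s_star, beta_tw = beta_tw,
                 sigma_s = sigma_s, k_phi = k_phi, k_g = k_g, k_h = k_h,
                 k_w = k_w, k_a = k_a, phi_max = phi_max,
                 sigma_phi = sigma_phi, sigma_a = sigma_a, sigma_u = sigma_u,
                 s_min = s_min, s_max = s_max, avoid_cutoff = avoid_cutoff),
            class = "species_params")
}

#' Built-in species presets
#'
#' Three contrasting flight signatures: the pigeon (moderate speed, fairly
#' direct goal-oriented flight), the gull (slower, drifting, wind-sensitive
#' flight with strong cross-wind compensation and heading noise) and the
#' peregrine falcon (fast and agile: high cruise speed, steep bank limit,
#' quick roll response and strong lateral perturbations).
#'
#' @param name One of `"pigeon"`, `"gull"`, `"peregrine"`.
#' @return A [species_params()] object.
#' @export
#' @examples
#' species_preset("pigeon")$s_star # 12 m/s cruise
species_preset <- function(name = c("pigeon", "gull", "peregrine")) {
  name <- match.arg(name)
  switch(name,
    pigeon = species_params("pigeon", k_s = 1.0, s_star = 12,
                            beta_tw = 0.25, sigma_s = 0.5, k_phi = 4,
                            k_g = 1.5, k_h = 0.02, k_w = 0.8, k_a = 3.0,
                            phi_max = 40 * pi / 180, sigma_phi = 0.08,
                            sigma_a = 0.7, sigma_u = 0.08),
    gull = species_params("gull", k_s = 0.8, s_star = 10, beta_tw = 0.35,
                          sigma_s = 0.4, k_phi = 3, k_g = 1.0, k_h = 0.018,
                          k_w = 1.8, k_a = 3.0, phi_max = 35 * pi / 180,
                          sigma_phi = 0.06, sigma_a = 0.5, sigma_u = 0.10),
    peregrine = species_params("peregrine", k_s = 1.5, s_star = 22,
                               beta_tw = 0.15, sigma_s = 0.8, k_phi = 6,
                               k_g = 2.5, k_h = 0.025, k_w = 0.5, k_a = 3.5,
                               phi_max = 70 * pi / 180, sigma_phi = 0.10,
                               sigma_a = 1.0, sigma_u = 0.07))
}

#' Bird state
#'
#' Instantaneous state of a bird agent: position, unit heading vector,
#' airspeed and bank angle.
#'
#' @param x Position (m), length 3.
#' @param u Heading vector, length 3; normalized internally.
#' @param s Airspeed (m/s), > 0.
#' @param phi Bank angle (rad); positive bank turns left.
#' @return An object of class `bird_state`.
#' @export
bird_state <- function(x = c(0, 0, 40), u = c(1, 0, 0), s = 12, phi = 0) {
  stopifnot(length(x) == 3, is.finite(x), length(u) == 3, is.finite(u))
  n <- sqrt(sum(u^2))
  if (n < 1e-12) stop("heading must be non-zero")
  if (!is.finite(s) || s <= 0) stop("airspeed must be positive")
  structure(list(x = as.numeric(x), u = as.numeric(u) / n, s = s,
                 phi = phi),
            class = "bird_state")
}

#' Quadrotor parameters
#'
#' Point-mass PID waypoint controller parameters for the simplified
#' quadrotor: PID gains, horizontal/vertical acceleration saturation, tilt
#' and tilt-rate limits on the thrust axis, thrust saturation, obstacle
#' avoidance gain, control and yaw noise, and the target altitude.
#'
#' @param mass Mass (kg).
#' @param kp,kd,ki PID gains (per axis).
#' @param a_h_max,a_v_max Horizontal / vertical acceleration saturation
#'   (m/s^2).
#' @param tilt_max Maximum thrust-axis tilt from vertical (rad), < pi/2.
#' @param tilt_rate_max Maximum tilt rate (rad/s).
#' @param thrust_max Maximum thrust (N); default 2.5 hover thrusts.
#' @param k_a_drone Obstacle avoidance strength.
#' @param sigma_ctrl Control acceleration noise (m/s^2).
#' @param yaw_rate_max Maximum yaw rate (rad/s).
#' @param sigma_yaw Yaw noise amplitude (rad s^-1/2).
#' @param h_star Target altitude (m).
#' @param avoid_cutoff Obstacle repulsion cutoff distance (m).
#' @return An object of class `drone_params`.
#' @export
drone_params <- function(mass = 1.2, kp = 1.2, kd = 1.8, ki = 0.05,
                         a_h_max = 4, a_v_max = 3,
                         tilt_max = 35 * pi / 180, tilt_rate_max = 2,
                         thrust_max = 2.5 * mass * GRAVITY,
                         k_a_drone = 3.0, sigma_ctrl = 0.15,
                         yaw_rate_max = 2, sigma_yaw = 0.05, h_star = 30,
                         avoid_cutoff = 25) {
  pos <- c(mass = mass, kp = kp, kd = kd, ki = ki, a_h_max = a_h_max,
           a_v_max = a_v_max, tilt_max = tilt_max,
           tilt_rate_max = tilt_rate_max, thrust_max = thrust_max,
           yaw_rate_max = yaw_rate_max, h_star = h_star)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("drone parameters must be positive")
  if (tilt_max >= pi / 2) stop("tilt_max must be below pi/2")
  if (sigma_ctrl < 0 || sigma_yaw < 0 || k_a_drone < 0)
    stop("noise amplitudes and gains must be non-negative")
  structure(list(mass = mass, kp = kp, kd = kd, ki = ki, a_h_max = a_h_max,
                 a_v_max = a_v_max, tilt_max = tilt_max,
                 tilt_rate_max = tilt_rate_max, thrust_max = thrust_max,
                 k_a_drone = k_a_drone, sigma_ctrl = sigma_ctrl,
                 yaw_rate_max = yaw_rate_max, sigma_yaw = sigma_yaw,
                 h_star = h_star, avoid_cutoff = avoid_cutoff),
            class = "drone_params")
}

#' Drone state
#'
#' @param x Position (m), length 3 (z >= 0).
#' @param v Velocity (m/s), length 3.
#' @param t_hat Thrust direction unit vector; normalized internally.
#' @param psi Yaw angle (rad).
#' @param e_int Integral position error (m s), length 3.
#' @return An object of class `drone_state`.
#' @export
drone_state <- function(x = c(0, 0, 0), v = c(0, 0, 0),
                        t_hat = c(0, 0, 1), psi = 0, e_int = c(0, 0, 0)) {
  stopifnot(length(x) == 3, is.finite(x), length(v) == 3, is.finite(v),
            length(t_hat) == 3, is.finite(t_hat), length(e_int) == 3)
  n <- sqrt(sum(t_hat^2))
  if (n < 1e-12) stop("thrust direction must be non-zero")
  if (x[3] < 0) stop("altitude must be non-negative")
  structure(list(x = as.numeric(x), v = as.numeric(v),
                 t_hat = as.numeric(t_hat) / n, psi = psi,
                 e_int = as.numeric(e_int)),
            class = "drone_state")
}

#' Coordinated-turn radius
#'
#' Closed-form banked-turn relation `tan(phi) = V^2 / (g R)`, solved for the
#' turn radius `R = V^2 / (g tan(phi))`.
#'
#' @param phi Bank angle (rad), in (0, pi/2).
#' @param V True airspeed (m/s), > 0.
#' @return Turn radius (m).
#' @export
#' @examples
#' turn_radius(45 * pi / 180, 9.81) # 9.81 m
turn_radius <- function(phi, V) {
  if (any(!is.finite(phi)) || any(phi <= 0) || any(phi >= pi / 2))
    stop("phi must lie in (0, pi/2)")
  if (any(!is.finite(V)) || any(V <= 0)) stop("V must be positive")
  V^2 / (GRAVITY * tan(phi))
}

#' Coordinated-turn yaw rate
#'
#' `psi' = V / R = g tan(phi) / V`; satisfies `yaw_rate * turn_radius = V`
#' exactly.
#'
#' @inheritParams turn_radius
#' @return Yaw rate (rad/s).
#' @export
yaw_rate <- function(phi, V) {
  if (any(!is.finite(phi)) || any(phi <= 0) || any(phi >= pi / 2))
    stop("phi must lie in (0, pi/2)")
  if (any(!is.finite(V)) || any(V <= 0)) stop("V must be positive")
  GRAVITY * tan(phi) / V
}

#' Rodrigues rotation
#'
#' Rotates a vector about a unit axis by a given angle; norm-preserving.
#'
#' @param v Vector to rotate, length 3.
#' @param axis Unit rotation axis, length 3.
#' @param angle Rotation angle (rad).
#' @return The rotated vector.
#' @export
rodrigues_rotate <- function(v, axis, angle) {
  stopifnot(length(v) == 3, is.finite(v), length(axis) == 3,
            is.finite(axis), is.finite(angle))
  cpp_rodrigues(as.numeric(v), as.numeric(axis), angle)
}

#' Behavioural acceleration command for a bird
#'
#' Sum of goal attraction (projected perpendicular to the heading and scaled
#' by airspeed), altitude hold, cross-wind compensation, inverse-square
#' obstacle repulsion within the cutoff, and (optionally) lateral Gaussian
#' noise projected perpendicular to the heading.
#'
#' @param bird A [bird_state()].
#' @param sp A [species_params()].
#' @param env An [environment_state()].
#' @param noise If `FALSE`, the random lateral component is omitted (useful
#'   for deterministic checks); when `TRUE` it draws from R's RNG.
#' @return Commanded acceleration (m/s^2), length 3.
#' @export
bird_behavioral_accel <- function(bird, sp, env, noise = TRUE) {
  stopifnot(inherits(bird, "bird_state"), inherits(sp, "species_params"),
            inherits(env, "environment_state"))
  cpp_bird_accel(bird$x, bird$u, bird$s, unclass(sp), unclass(env),
                 env$wind, env$gust, noise)
}

#' Desired bank angle from an acceleration command
#'
#' Converts the horizontal lateral part of a commanded acceleration
#' (perpendicular to the heading) into a bank angle via
#' `atan(|a_lat| / g)`, signed by turn direction (positive = left) and
#' saturated at the species maximum.
#'
#' @param a_cmd Commanded acceleration (m/s^2), length 3.
#' @param u Heading unit vector, length 3.
#' @param phi_max Maximum bank angle (rad).
#' @return Desired bank angle (rad), in `[-phi_max, phi_max]`.
#' @export
desired_bank <- function(a_cmd, u, phi_max) {
  stopifnot(length(a_cmd) == 3, is.finite(a_cmd), length(u) == 3)
  cpp_desired_bank(as.numeric(a_cmd), as.numeric(u), phi_max)
}

#' Advance a bird by one time step
#'
#' One Euler-Maruyama step of the kinematic stochastic model: bank-angle
#' relaxation toward the commanded bank with roll noise, realized
#' perpendicular acceleration `g tan(phi)` laterally plus the vertical
#' command (total capped at `g tan(phi_max)`), heading rotation
#' `u' = omega x u` with `omega = (u x a_L)/s` applied via a Rodrigues
#' rotation, orthogonal heading noise, airspeed relaxation with tailwind
#' coupling (clamped to the species bounds), and position advance by
#' airspeed plus wind. The environment's gust is held fixed; advance it
#' separately with [step_gust()].
#'
#' @inheritParams bird_behavioral_accel
#' @param dt Time step (s), > 0.
#' @return The updated [bird_state()].
#' @export
bird_step <- function(bird, sp, env, dt) {
  stopifnot(inherits(bird, "bird_state"), inherits(sp, "species_params"),
            inherits(env, "environment_state"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  out <- cpp_bird_step(unclass(bird), unclass(sp), unclass(env), env$wind,
                       env$gust, dt)
  structure(out, class = "bird_state")
}

#' Advance a drone by one time step
#'
#' One step of the point-mass PID quadrotor: PID desired acceleration (with
#' the goal altitude replaced by the target altitude `h_star`), wind
#' compensation, obstacle avoidance and control noise; separate horizontal
#' and vertical acceleration saturation; rate-limited, tilt-capped rotation
#' of the thrust axis toward the desired thrust direction; thrust obtained
#' by projecting the desired force on the thrust axis and saturating;
#' semi-implicit Euler position update with a ground constraint; and
#' rate-limited noisy yaw tracking of the velocity (or goal) heading.
#'
#' @param drone A [drone_state()].
#' @param dp A [drone_params()].
#' @param env An [environment_state()].
#' @param dt Time step (s), > 0.
#' @return The updated [drone_state()]; attributes `tilt` (rad) and
#'   `thrust` (N) report the realized tilt and thrust of the step.
#' @export
drone_step <- function(drone, dp, env, dt) {
  stopifnot(inherits(drone, "drone_state"), inherits(dp, "drone_params"),
            inherits(env, "environment_state"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  out <- cpp_drone_step(unclass(drone), unclass(dp), unclass(env), env$wind,
                        env$gust, dt)
  st <- structure(out[c("x", "v", "t_hat", "psi", "e_int")],
                  class = "drone_state")
  attr(st, "tilt") <- out$tilt
  attr(st, "thrust") <- out$thrust
  st
}
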