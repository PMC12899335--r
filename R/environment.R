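#' Wind field configuration
#'
#' Describes the three components of the wind field shared by every agent:
#' a constant base wind, a temporally correlated gust modelled as a
#' three-dimensional Ornstein-Uhlenbeck (OU) process, and a "thermal" updraft
#' whose vertical velocity falls off as a Gaussian bump of the horizontal
#' distance from a fixed centre.
#'
#' @param w_base Base wind vector (m/s), length 3.
#' @param tau_gust Gust correlation time (s), > 0.
#' @param sigma_gust Stationary per-axis gust standard deviation (m/s), >= 0.
#' @param thermal_center Horizontal centre of the thermal (m), length 2.
#' @param thermal_strength Peak vertical thermal wind (m/s).
#' @param thermal_radius Thermal length scale (m), > 0.
#'
#' @return An object of class `wind_config`.
#' @export
#' @examples
#' w <- wind_config(sigma_gust = 0)
wind_config <- function(w_base = c(1.5, 0.5, 0), tau_gust = 2,
                        sigma_gust = 0.6, thermal_center = c(0, 0),
                        thermal_strength = 1, thermal_radius = 40) {
  stopifnot(length(w_base) == 3, is.finite(w_base),
            length(thermal_center) == 2, is.finite(thermal_center))
  if (!is.finite(tau_gust) || tau_gust <= 0)
    stop("tau_gust must be positive")
  if (!is.finite(sigma_gust) || sigma_gust < 0)
    stop("sigma_gust must be non-negative")
  if (!is.finite(thermal_radius) || thermal_radius <= 0)
    stop("thermal_radius must be positive")
  structure(list(w_base = as.numeric(w_base), tau_gust = tau_gust,
                 sigma_gust = sigma_gust,
                 thermal_center = as.numeric(thermal_center),
                 thermal_strength = thermal_strength,
                 thermal_radius = thermal_radius),
            class = "wind_config")
}

#' Environment state
#'
#' The static scene (goal waypoint, preferred altitude, obstacle positions)
#' plus the wind configuration and the current OU gust vector. The gust is
#' the only time-varying element; it is advanced by [step_gust()].
#'
#' @param wind A [wind_config()].
#' @param goal Goal waypoint (m), length 3.
#' @param h_pref Preferred flight altitude (m), >= 0.
#' @param obstacles Matrix of obstacle positions (one row per obstacle,
#'   3 columns) or `NULL` for none.
#' @param gust Initial gust vector (m/s), length 3.
#'
#' @return An object of class `environment_state`.
#' @export
environment_state <- function(wind = wind_config(), goal = c(100, 50, 40),
                              h_pref = 40, obstacles = NULL,
                              gust = c(0, 0, 0)) {
  stopifnot(inherits(wind, "wind_config"), length(goal) == 3,
            is.finite(goal), length(gust) == 3, is.finite(gust))
  if (!is.finite(h_pref) || h_pref < 0)
    stop("h_pref must be non-negative")
  if (is.null(obstacles)) {
    obstacles <- matrix(numeric(0), nrow = 0, ncol = 3)
  } else {
    obstacles <- matrix(as.numeric(obstacles), ncol = 3)
  }
  structure(list(wind = wind, gust = as.numeric(gust),
                 goal = as.numeric(goal), h_pref = h_pref,
                 obstacles = obstacles),
            class = "environment_state")
}

#' Advance the Ornstein-Uhlenbeck gust by one time step
#'
#' Uses the exact conditional-Gaussian OU discretization
#' `gust' = gust * exp(-dt/tau) + sigma * sqrt(1 - exp(-2 dt/tau)) * eta`,
#' with `eta` standard normal per axis, so the stationary per-axis standard
#' deviation equals `sigma_gust` for any step size.
#'
#' @param env An [environment_state()].
#' @param dt Time step (s), > 0.
#' @return The environment with its gust vector replaced by the update.
#' @export
step_gust <- function(env, dt) {
  stopifnot(inherits(env, "environment_state"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  env$gust <- cpp_step_gust(env$gust, env$wind$tau_gust,
                            env$wind$sigma_gust, dt)
  env
}

#' Total wind at a position
#'
#' Deterministic given the current environment state: base wind plus the
#' current gust plus the vertical thermal component
#' `thermal_strength * exp(-d^2 / (2 thermal_radius^2))`, where `d` is the
#' horizontal distance from the thermal centre.
#'
#' @param env An [environment_state()].
#' @param x Position (m), length 3.
#' @return Wind velocity vector (m/s), length 3.
#' @export
wind_at <- function(env, x) {
  stopifnot(inherits(env, "environment_state"), length(x) == 3,
            is.finite(x))
  cpp_wind_at(env$wind, env$gust, as.numeric(x))
}
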