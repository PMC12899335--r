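#' Trajectory record
#'
#' The labeled interchange unit: a class flag, an optional species label,
#' the sampling step, an ordered sequence of 3-D positions and the seed the
#' trajectory was generated from.
#'
#' @param positions Numeric matrix, one row per time step, columns x, y, z
#'   (m).
#' @param is_drone Logical class flag (`TRUE` = drone, `FALSE` = bird).
#' @param species Species label for birds, or `NA`.
#' @param dt Sampling step (s).
#' @param seed Integer seed, or `NA`.
#' @return An object of class `trajectory_record`.
#' @export
trajectory_record <- function(positions, is_drone, species = NA_character_,
                              dt = 0.03, seed = NA_integer_) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (nrow(positions) < 1 || any(!is.finite(positions)))
    stop("positions must be a non-empty finite n x 3 matrix")
  seed <- if (is.na(seed)) NA_integer_ else as.integer(seed)
  structure(list(is_drone = isTRUE(is_drone), species = species, dt = dt,
                 positions = positions, seed = seed),
            class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("<trajectory_record> %s%s, %d positions, dt = %g s\n",
              if (x$is_drone) "drone" else "bird",
              if (is.na(x$species)) "" else paste0(" (", x$species, ")"),
              nrow(x$positions), x$dt))
  invisible(x)
}

# randomized scene for one trajectory (drawn from the current RNG state):
# goal uniform in a 200 m box at 20-60 m altitude, 0-3 obstacles, thermal
# centre uniform in the same box; the preferred/target altitude follows the
# goal altitude
random_environment <- function() {
  goal <- c(runif(2, -100, 100), runif(1, 20, 60))
  n_obs <- sample(0:3, 1)
  obstacles <- if (n_obs > 0) {
    cbind(runif(n_obs, -100, 100), runif(n_obs, -100, 100),
          runif(n_obs, 10, 60))
  } else NULL
  wind <- wind_config(thermal_center = runif(2, -100, 100))
  environment_state(wind = wind, goal = goal, h_pref = goal[3],
                    obstacles = obstacles)
}

#' Simulate one labeled trajectory
#'
#' Runs the stochastic simulator in discrete time: each step first advances
#' the Ornstein-Uhlenbeck gust, then steps the agent (bird kinematic model or
#' PID quadrotor). The record contains `floor(horizon/dt) + 1` positions
#' (initial state included) and is bit-reproducible given the seed.
#'
#' When no environment is supplied, the scene, the initial state and (for
#' birds) the heading are randomized from the seed: birds start inside a
#' 100 m box at 20-60 m altitude with a uniform horizontal heading, cruise
#' airspeed and level bank; the drone starts at rest on the ground below the
#' goal.
#'
#' @param kind `"bird"` or `"drone"`.
#' @param preset Species preset name for birds (see [species_preset()]);
#'   ignored for drones.
#' @param env An [environment_state()], or `NULL` to randomize one from the
#'   seed.
#' @param horizon Simulation horizon T (s), > 0.
#' @param dt Time step (s), > 0.
#' @param seed Integer seed.
#' @return A [trajectory_record()]. Per-step diagnostics are attached as
#'   attributes: `speed` and `phi` for birds, `tilt` and `thrust` for
#'   drones.
#' @export
simulate_trajectory <- function(kind = c("bird", "drone"),
                                preset = "pigeon", env = NULL,
                                horizon = 100, dt = 0.03, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be positive")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  set.seed(seed)
  if (is.null(env)) env <- random_environment()
  stopifnot(inherits(env, "environment_state"))
  n_steps <- floor(horizon / dt)

  if (kind == "bird") {
    sp <- species_preset(preset)
    theta <- runif(1, 0, 2 * pi)
    b0 <- bird_state(x = c(runif(2, -50, 50), runif(1, 20, 60)),
                     u = c(cos(theta), sin(theta), 0), s = sp$s_star,
                     phi = 0)
    sim <- cpp_simulate_bird(unclass(b0), unclass(sp), unclass(env),
                             env$wind, env$gust, n_steps, dt)
    rec <- trajectory_record(sim$positions, is_drone = FALSE,
                             species = sp$name, dt = dt, seed = seed)
    attr(rec, "speed") <- sim$speed
    attr(rec, "phi") <- sim$phi
  } else {
    dp <- drone_params(h_star = env$h_pref)
    d0 <- drone_state(x = c(env$goal[1], env$goal[2], 0))
    sim <- cpp_simulate_drone(unclass(d0), unclass(dp), unclass(env),
                              env$wind, env$gust, n_steps, dt)
    rec <- trajectory_record(sim$positions, is_drone = TRUE,
                             species = NA_character_, dt = dt, seed = seed)
    attr(rec, "tilt") <- sim$tilt
    attr(rec, "thrust") <- sim$thrust
  }
  rec
}

#' Write a trajectory record to JSON
#'
#' Canonical schema: `is_drone` (boolean), `movement_history` (list of
#' `[x, y, z]` triples) and the optional keys `species`, `dt` and `seed`.
#' Coordinates are serialized at 17 significant digits (the shortest length
#' guaranteed to reconstruct every IEEE double exactly) so that a write/read
#' round trip is bit-exact.
#'
#' @param record A [trajectory_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_json <- function(record, path) {
  stopifnot(inherits(record, "trajectory_record"))
  obj <- list(is_drone = record$is_drone)
  if (!is.na(record$species)) obj$species <- record$species
  if (!is.na(record$dt)) obj$dt <- record$dt
  if (!is.na(record$seed)) obj$seed <- as.integer(record$seed)
  obj$movement_history <- record$positions
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a trajectory record from JSON
#'
#' Unknown extra keys are ignored. A missing `movement_history` key or
#' malformed coordinates raise a parse error naming the offending key. A
#' missing class flag is an error when `require_label = TRUE` (training
#' data) and yields `is_drone = NA` otherwise (prediction input).
#'
#' @param path JSON file path.
#' @param require_label Whether the class flag must be present.
#' @return A [trajectory_record()].
#' @export
read_trajectory_json <- function(path, require_label = TRUE) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$movement_history))
    stop("missing 'movement_history' in ", path)
  pos <- obj$movement_history
  if (is.list(pos)) pos <- do.call(rbind, pos)
  pos <- try(matrix(as.numeric(pos), ncol = 3), silent = TRUE)
  if (inherits(pos, "try-error") || any(!is.finite(pos)))
    stop("malformed coordinates in 'movement_history' in ", path)
  is_drone <- obj$is_drone
  if (is.null(is_drone)) {
    if (require_label) stop("missing 'is_drone' label in ", path)
    is_drone <- NA
  }
  rec <- trajectory_record(
    pos, is_drone = isTRUE(is_drone),
    species = if (is.null(obj$species)) NA_character_ else obj$species,
    dt = if (is.null(obj$dt)) NA_real_ else obj$dt,
    seed = if (is.null(obj$seed)) NA_integer_ else as.integer(obj$seed))
  if (is.na(is_drone)) rec$is_drone <- NA
  rec
}

#' Downsample a trajectory to the classifier length
#'
#' Retains positions at uniformly spaced indices, always including the first
#' and last point; records shorter than the target are returned unchanged
#' (no upsampling). The sampling step is rescaled by the stride.
#'
#' @param record A [trajectory_record()].
#' @param target_len Target number of positions, >= 2.
#' @return A [trajectory_record()] with at most `target_len` positions.
#' @export
downsample <- function(record, target_len = 100) {
  stopifnot(inherits(record, "trajectory_record"))
  if (!is.finite(target_len) || target_len < 2)
    stop("target_len must be at least 2")
  n <- nrow(record$positions)
  if (n <= target_len) return(record)
  idx <- round(seq(1, n, length.out = target_len))
  out <- record
  out$positions <- record$positions[idx, , drop = FALSE]
  out$dt <- record$dt * (n - 1) / (target_len - 1)
  attr(out, "speed") <- NULL
  attr(out, "phi") <- NULL
  attr(out, "tilt") <- NULL
  attr(out, "thrust") <- NULL
  out
}

#' Generate a balanced labeled dataset
#'
#' Writes `2 * n_per_class` JSON trajectory files (birds cycling uniformly
#' over the pigeon, gull and peregrine presets, plus drones) with per-file
#' seeds derived deterministically from the global seed, and a
#' `manifest.json` describing the run.
#'
#' @param n_per_class Number of trajectories per class, >= 1.
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param horizon,dt Simulation horizon (s) and step (s).
#' @param verbose If `TRUE`, log one line per file to standard error.
#' @return The manifest, invisibly (class `dataset_manifest`).
#' @export
generate_dataset <- function(n_per_class, out_dir, seed = 1L,
                             horizon = 100, dt = 0.03, verbose = FALSE) {
  if (!is.finite(n_per_class) || n_per_class < 1)
    stop("n_per_class must be at least 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  file_seeds <- sample.int(.Machine$integer.max, 2 * n_per_class)
  cycle <- c("pigeon", "gull", "peregrine")

  files <- character(0); kinds <- character(0); specieses <- character(0)
  used_seeds <- integer(0)
  for (i in seq_len(n_per_class)) {
    spname <- cycle[(i - 1) %% 3 + 1]
    fseed <- file_seeds[2 * i - 1]
    rec <- simulate_trajectory("bird", preset = spname, horizon = horizon,
                               dt = dt, seed = fseed)
    f <- sprintf("bird_%04d_%s.json", i, spname)
    write_trajectory_json(rec, file.path(out_dir, f))
    if (verbose) message(sprintf("wrote %s kind=bird species=%s seed=%d",
                                 f, spname, fseed))
    files <- c(files, f); kinds <- c(kinds, "bird")
    specieses <- c(specieses, spname); used_seeds <- c(used_seeds, fseed)

    fseed <- file_seeds[2 * i]
    rec <- simulate_trajectory("drone", horizon = horizon, dt = dt,
                               seed = fseed)
    f <- sprintf("drone_%04d.json", i)
    write_trajectory_json(rec, file.path(out_dir, f))
    if (verbose) message(sprintf("wrote %s kind=drone seed=%d", f, fseed))
    files <- c(files, f); kinds <- c(kinds, "drone")
    specieses <- c(specieses, NA_character_)
    used_seeds <- c(used_seeds, fseed)
  }

  manifest <- list(directory = normalizePath(out_dir),
                   n_bird = n_per_class, n_drone = n_per_class,
                   seed = as.integer(seed),
                   config = list(horizon = horizon, dt = dt,
                                 species_cycle = cycle),
                   files = data.frame(file = files, kind = kinds,
                                      species = specieses,
                                      seed = used_seeds,
                                      stringsAsFactors = FALSE))
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE,
                              dataframe = "rows"),
             file.path(out_dir, "manifest.json"))
  class(manifest) <- "dataset_manifest"
  invisible(manifest)
}

#' Load every trajectory JSON file in a directory
#'
#' @param dir Directory containing `*.json` trajectory files (a
#'   `manifest.json` is skipped).
#' @param require_label Whether class flags must be present.
#' @return A list of [trajectory_record()] objects.
#' @export
load_dataset <- function(dir, require_label = TRUE) {
  paths <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  paths <- paths[basename(paths) != "manifest.json"]
  if (length(paths) == 0) return(list())
  lapply(paths, read_trajectory_json, require_label = require_label)
}
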