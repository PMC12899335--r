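#' Pinhole camera model
#'
#' An ideal pinhole camera (no lens distortion or rolling shutter), rigidly
#' fixed at the origin and looking straight up: world `z` is depth along the
#' optical axis, world `x`/`y` map to image columns/rows. Image coordinates
#' use `y = 0` at the top.
#'
#' @param width,height Image size (px).
#' @param fov Horizontal field of view (rad); sets both focal lengths via
#'   [focal_from_fov()] unless `f_x`/`f_y` are given.
#' @param f_x,f_y Focal lengths (px).
#' @param c_x,c_y Principal point (px); defaults to the image centre.
#' @param skew Skew factor (px), usually 0.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(width = 640, height = 480, fov = 60 * pi / 180,
                         f_x = NULL, f_y = NULL, c_x = (width - 1) / 2,
                         c_y = (height - 1) / 2, skew = 0) {
  if (is.null(f_x)) f_x <- focal_from_fov(fov, width)
  if (is.null(f_y)) f_y <- f_x
  if (f_x <= 0 || f_y <= 0) stop("focal lengths must be positive")
  if (c_x < 0 || c_x >= width || c_y < 0 || c_y >= height)
    stop("principal point must lie inside the image")
  structure(list(f_x = f_x, f_y = f_y, c_x = c_x, c_y = c_y, skew = skew,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_model")
}

#' Focal length from field of view
#'
#' `f = (N_px / 2) / tan(FOV / 2)`.
#'
#' @param fov Field of view (rad), in (0, pi).
#' @param n_px Sensor extent along the corresponding dimension (px).
#' @return Focal length (px).
#' @export
#' @examples
#' focal_from_fov(pi / 2, 1000) # 500 px
focal_from_fov <- function(fov, n_px) {
  if (any(!is.finite(fov)) || any(fov <= 0) || any(fov >= pi))
    stop("fov must lie in (0, pi)")
  (n_px / 2) / tan(fov / 2)
}

#' Project a world point into the image
#'
#' Homogeneous pinhole projection with the calibration matrix
#' `K = [[f_x, skew, c_x], [0, f_y, c_y], [0, 0, 1]]`. Depth is the world
#' coordinate along the (vertical) optical axis and is returned for apparent
#' size computation.
#'
#' @param cam A [camera_model()].
#' @param x_world World point (m), length 3.
#' @return A list with `u`, `v` (px), `depth` (m) and `in_view` (logical:
#'   positive depth and inside the image bounds). Points at or behind the
#'   camera plane have `in_view = FALSE` and `NA` pixel coordinates.
#' @export
project <- function(cam, x_world) {
  stopifnot(inherits(cam, "camera_model"), length(x_world) == 3)
  depth <- x_world[3]
  if (!is.finite(depth) || depth <= 0)
    return(list(u = NA_real_, v = NA_real_, depth = depth, in_view = FALSE))
  u <- cam$f_x * x_world[1] / depth + cam$skew * x_world[2] / depth + cam$c_x
  v <- cam$f_y * x_world[2] / depth + cam$c_y
  list(u = u, v = v, depth = depth,
       in_view = u >= 0 && u <= cam$width - 1 && v >= 0 &&
         v <= cam$height - 1)
}

#' Apparent size of an object
#'
#' On-sensor extent (px) of an object of physical size `l_phys` at a given
#' depth: `f_x * l_phys / depth` (reciprocal-depth scaling).
#'
#' @param cam A [camera_model()].
#' @param l_phys Physical size (m).
#' @param depth Depth along the optical axis (m), > 0.
#' @return Apparent size (px).
#' @export
apparent_size <- function(cam, l_phys, depth) {
  stopifnot(inherits(cam, "camera_model"))
  if (any(!is.finite(depth)) || any(depth <= 0))
    stop("depth must be positive")
  cam$f_x * l_phys / depth
}

#' Procedural sky configuration
#'
#' Vertical colour gradient from a zenith colour to a near-horizon colour,
#' plus semi-transparent clouds: Gaussian blobs whose centres drift
#' sinusoidally in time. The blob sum is normalized by its maximum,
#' attenuated linearly toward the horizon row and clipped to `[0, 1]`.
#'
#' @param c_top,c_bottom,c_cloud RGB colours (0-255), length 3.
#' @param alpha_cloud Maximum cloud opacity in `[0, 1]`.
#' @param n_blobs Number of cloud blobs.
#' @param seed Seed for the blob layout.
#' @return An object of class `sky_config`.
#' @export
sky_config <- function(c_top = c(40, 80, 170), c_bottom = c(200, 220, 245),
                       c_cloud = c(250, 250, 252), alpha_cloud = 0.55,
                       n_blobs = 6, seed = 1L) {
  stopifnot(length(c_top) == 3, length(c_bottom) == 3, length(c_cloud) == 3)
  if (any(c(c_top, c_bottom, c_cloud) < 0) ||
      any(c(c_top, c_bottom, c_cloud) > 255))
    stop("colours must lie in [0, 255]")
  if (alpha_cloud < 0 || alpha_cloud > 1)
    stop("alpha_cloud must lie in [0, 1]")
  blobs <- NULL
  if (n_blobs > 0) {
    set.seed(seed)
    blobs <- data.frame(cx = runif(n_blobs, 0, 1), cy = runif(n_blobs, 0, 1),
                        radius = runif(n_blobs, 0.05, 0.2),
                        amp_x = runif(n_blobs, 0.01, 0.05),
                        amp_y = runif(n_blobs, 0.005, 0.02),
                        freq_x = runif(n_blobs, 0.02, 0.1),
                        freq_y = runif(n_blobs, 0.02, 0.1))
  }
  structure(list(c_top = c_top, c_bottom = c_bottom, c_cloud = c_cloud,
                 alpha_cloud = alpha_cloud, blobs = blobs),
            class = "sky_config")
}

# cloud opacity mask at time t: normalized Gaussian blob sum with sinusoidal
# drift, linear horizon attenuation, clipped to [0, 1]
cloud_mask <- function(sky, width, height, t) {
  m <- matrix(0, nrow = height, ncol = width)
  if (is.null(sky$blobs) || nrow(sky$blobs) == 0) return(m)
  xs <- matrix(seq_len(width) - 1, nrow = height, ncol = width, byrow = TRUE)
  ys <- matrix(seq_len(height) - 1, nrow = height, ncol = width)
  for (i in seq_len(nrow(sky$blobs))) {
    b <- sky$blobs[i, ]
    cx <- (b$cx + b$amp_x * sin(2 * pi * b$freq_x * t)) * (width - 1)
    cy <- (b$cy + b$amp_y * sin(2 * pi * b$freq_y * t)) * (height - 1)
    r <- b$radius * width
    m <- m + exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * r^2))
  }
  mx <- max(m)
  if (mx > 0) m <- m / mx
  att <- 1 - (seq_len(height) - 1) / (height - 1) # thinner near the horizon
  m <- m * att
  pmin(pmax(m, 0), 1)
}

#' Render one frame
#'
#' Row-gradient sky (`alpha = y / (H - 1)`, linear blend from the zenith to
#' the horizon colour), alpha-blended clouds
#' `I = (1 - alpha_cloud M) C_sky + alpha_cloud M C_cloud`, and targets drawn
#' as filled discs at their projected positions.
#'
#' @param cam A [camera_model()].
#' @param sky A [sky_config()].
#' @param t Time (s), drives cloud drift.
#' @param targets Optional data frame or list of lists with `u`, `v`
#'   (px) and `size` (px diameter) per target.
#' @param target_color RGB colour of targets (0-255).
#' @return An `height x width x 3` array of RGB values in `[0, 255]`.
#' @export
render_frame <- function(cam, sky, t = 0, targets = NULL,
                         target_color = c(30, 30, 30)) {
  stopifnot(inherits(cam, "camera_model"), inherits(sky, "sky_config"))
  h <- cam$height; w <- cam$width
  alpha <- (seq_len(h) - 1) / (h - 1)
  m <- cloud_mask(sky, w, h, t)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    c_sky <- (1 - alpha) * sky$c_top[ch] + alpha * sky$c_bottom[ch]
    base <- matrix(c_sky, nrow = h, ncol = w)
    img[, , ch] <- (1 - sky$alpha_cloud * m) * base +
      sky$alpha_cloud * m * sky$c_cloud[ch]
  }
  if (!is.null(targets) && length(targets) > 0) {
    tg <- if (is.data.frame(targets)) split(targets, seq_len(nrow(targets)))
          else targets
    for (target in tg) {
      if (!is.finite(target$u) || !is.finite(target$v)) next
      r <- max(target$size / 2, 0.5)
      cols <- max(1, ceiling(target$u - r)):min(w, floor(target$u + r) + 1)
      rows <- max(1, ceiling(target$v - r)):min(h, floor(target$v + r) + 1)
      for (yy in rows) for (xx in cols) {
        if ((xx - 1 - target$u)^2 + (yy - 1 - target$v)^2 <= r^2)
          img[yy, xx, ] <- target_color
      }
    }
  }
  img
}

#' Write a rendered frame as PNG
#'
#' @param img Array from [render_frame()] (values in `[0, 255]`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), target = path)
  invisible(path)
}

#' Encode a trajectory as an image-plane track
#'
#' Projects each 3-D position through the camera and computes the apparent
#' size of an object of physical size `l_phys` at that depth. Frames behind
#' the camera or outside the image are flagged out of view.
#'
#' @param cam A [camera_model()].
#' @param record A [trajectory_record()].
#' @param l_phys Physical target size (m).
#' @return A data frame with columns `u`, `v`, `size` and `in_view`, one
#'   row per frame.
#' @export
encode_image_plane_track <- function(cam, record, l_phys = 0.6) {
  stopifnot(inherits(cam, "camera_model"),
            inherits(record, "trajectory_record"))
  n <- nrow(record$positions)
  out <- data.frame(u = rep(NA_real_, n), v = NA_real_, size = NA_real_,
                    in_view = FALSE)
  for (i in seq_len(n)) {
    p <- project(cam, record$positions[i, ])
    out$u[i] <- p$u; out$v[i] <- p$v; out$in_view[i] <- p$in_view
    if (is.finite(p$depth) && p$depth > 0)
      out$size[i] <- apparent_size(cam, l_phys, p$depth)
  }
  out
}

#' Render a trajectory to PNG frames
#'
#' Convenience wrapper: projects the record frame by frame and writes one
#' PNG per (optionally strided) frame.
#'
#' @param record A [trajectory_record()].
#' @param out_dir Output directory.
#' @param cam A [camera_model()].
#' @param sky A [sky_config()].
#' @param l_phys Physical target size (m).
#' @param stride Keep every `stride`-th frame.
#' @return Paths of the written frames, invisibly.
#' @export
render_trajectory <- function(record, out_dir, cam = camera_model(),
                              sky = sky_config(), l_phys = 0.6,
                              stride = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  track <- encode_image_plane_track(cam, record, l_phys)
  idx <- seq(1, nrow(track), by = stride)
  paths <- character(0)
  for (k in seq_along(idx)) {
    i <- idx[k]
    tgt <- NULL
    if (isTRUE(track$in_view[i]))
      tgt <- list(list(u = track$u[i], v = track$v[i],
                       size = max(track$size[i], 1)))
    img <- render_frame(cam, sky, t = (i - 1) * record$dt, targets = tgt)
    p <- file.path(out_dir, sprintf("frame_%05d.png", k))
    write_frame_png(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
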