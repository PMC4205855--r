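# 2D random-walk simulator: Rayleigh step lengths with E[r^2] = 4 D dt,
# uniform step angles, optional drift or circular confinement; footprint
# rasterization (fixed cross, per-frame random connected shapes, split
# footprints) and image rendering over Gaussian background noise.

#' Simulation configuration
#'
#' Collects every parameter of the validation simulator.  Defaults mirror
#' the single-molecule imaging conditions the method was designed around:
#' 6.4 ms frame interval (156 frames/s), 160 nm pixels, 5-pixel
#' footprints, and a signal amplitude of 8 background s.d. so that
#' thresholding at `m + 4s` recovers the planted footprints.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param dt frame interval, s.
#' @param n_frames number of frames (>= 2).
#' @param pixel_size pixel size, um.
#' @param n_pixels footprint size.
#' @param image_shape `c(rows, cols)` of the simulated detector.
#' @param background `c(mean, sd)` of the Gaussian background intensity.
#' @param signal_amplitude intensity added to footprint pixels, in the same
#'   units; default `8 * background sd`.
#' @param mode `"random"`, `"directed"` or `"confined"`.
#' @param drift_velocity drift speed, um/s (directed mode); the default of
#'   50 um/s moves the particle 2 pixels per frame at the default frame
#'   interval, so directed transport dominates Brownian spreading at
#'   D around 1 um^2/s.
#' @param confinement_radius circle radius, um (confined mode; specular
#'   reflection at the boundary).
#' @param shape_mode `"fixed"` (plus-shaped footprint) or `"random"`
#'   (fresh random 8-connected shape each frame).
#' @param split_fraction fraction of frames whose footprint is split in two.
#' @param split_distance displacement of the split-off 2-pixel group, in
#'   pixels, applied in both x and y.
#' @param seed master seed; per-track seeds are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(D = 1.0, dt = 0.0064, n_frames = 300L,
                       pixel_size = 0.16, n_pixels = 5L,
                       image_shape = c(256L, 256L),
                       background = c(100, 10),
                       signal_amplitude = 8 * background[2],
                       mode = c("random", "directed", "confined"),
                       drift_velocity = 50, confinement_radius = 0.5,
                       shape_mode = c("fixed", "random"),
                       split_fraction = 0, split_distance = 2L,
                       seed = 1L) {
  mode <- match.arg(mode)
  shape_mode <- match.arg(shape_mode)
  stopifnot(D >= 0, dt > 0, n_frames >= 2L, pixel_size > 0,
            split_fraction >= 0, split_fraction <= 1, split_distance >= 0)
  structure(
    list(D = D, dt = dt, n_frames = as.integer(n_frames),
         pixel_size = pixel_size, n_pixels = as.integer(n_pixels),
         image_shape = as.integer(image_shape), background = background,
         signal_amplitude = signal_amplitude, mode = mode,
         drift_velocity = drift_velocity,
         confinement_radius = confinement_radius, shape_mode = shape_mode,
         split_fraction = split_fraction,
         split_distance = as.integer(split_distance),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Sample Brownian step displacements
#'
#' Step lengths follow the 2D normal-diffusion step-length density
#' `q(r) = r/(2 D dt) * exp(-r^2/(4 D dt))` (Rayleigh form), so that
#' `E[r^2] = 4 D dt` equals the MSD at lag `dt`.  Since
#' `r^2/(4 D dt)` is standard-exponential, draws use
#' `r = sqrt(4 D dt * rexp(n))`.  Step angles are uniform on
#' `[0, 2*pi)`.
#'
#' @param n number of steps.
#' @param D diffusion coefficient, um^2/s.
#' @param dt time lag, s.
#' @return list with `r` (lengths, um) and `theta` (angles, rad).
#' @export
sample_step <- function(n, D, dt) {
  stopifnot(D >= 0, dt > 0)
  list(r = sqrt(4 * D * dt * stats::rexp(n)),
       theta = stats::runif(n, 0, 2 * pi))
}

#' Simulate a single-particle trajectory
#'
#' Positions start at the origin and accumulate sampled steps.  Directed
#' mode adds `drift_velocity * dt` along +x each frame; confined mode
#' reflects the position specularly off a circle of
#' `confinement_radius` about the origin.
#'
#' @param config a [sim_config()].
#' @return object of class `trajectory`: data frame with `t` (s) and
#'   `x`, `y` (um), plus attributes `dt` and `pixel_size`.
#' @export
simulate_trajectory <- function(config) {
  n <- config$n_frames
  st <- sample_step(n - 1L, config$D, config$dt)
  dx <- st$r * cos(st$theta)
  dy <- st$r * sin(st$theta)
  if (config$mode == "directed") dx <- dx + config$drift_velocity * config$dt
  if (config$mode == "confined") {
    R <- config$confinement_radius
    x <- numeric(n); y <- numeric(n)
    for (i in 2:n) {
      px <- x[i - 1] + dx[i - 1]
      py <- y[i - 1] + dy[i - 1]
      rad <- sqrt(px^2 + py^2)
      if (rad > R) {                     # reflect across the boundary circle
        px <- px * (2 * R - rad) / rad
        py <- py * (2 * R - rad) / rad
        rad2 <- sqrt(px^2 + py^2)
        if (rad2 > R) { px <- px * R / rad2; py <- py * R / rad2 }
      }
      x[i] <- px; y[i] <- py
    }
  } else {
    x <- c(0, cumsum(dx))
    y <- c(0, cumsum(dy))
  }
  traj <- data.frame(t = (seq_len(n) - 1) * config$dt, x = x, y = y,
                     valid = TRUE)
  attr(traj, "dt") <- config$dt
  attr(traj, "pixel_size") <- config$pixel_size
  class(traj) <- c("trajectory", "data.frame")
  traj
}

# Canonical fixed 5-pixel footprint: a plus/cross, the symmetric connected
# 5-pixel shape.  Offsets (row, col) about the centre pixel.
cross_offsets <- function() {
  cbind(row = c(0L, -1L, 1L, 0L, 0L), col = c(0L, 0L, 0L, -1L, 1L))
}

# Grow a random connected shape of n pixels containing (0, 0) by
# edge-sharing (4-connected) accretion: repeatedly attach an unoccupied
# edge neighbour of a uniformly chosen member pixel.  Accretion keeps the
# shapes compact, like the brightest-pixel sets of a diffraction-limited
# spot; the result is trivially 8-connected as well.
random_shape <- function(n) {
  rows <- integer(n); cols <- integer(n)
  for (k in 2:n) {
    repeat {
      j <- sample.int(k - 1L, 1L)
      if (stats::runif(1) < 0.5) {
        dr <- sample(c(-1L, 1L), 1L); dc <- 0L
      } else {
        dr <- 0L; dc <- sample(c(-1L, 1L), 1L)
      }
      nr <- rows[j] + dr; nc <- cols[j] + dc
      if (!any(rows[seq_len(k - 1L)] == nr & cols[seq_len(k - 1L)] == nc)) {
        rows[k] <- nr; cols[k] <- nc
        break
      }
    }
  }
  cbind(row = rows, col = cols)
}

#' Rasterize a trajectory into per-frame footprints
#'
#' Each position maps to its nearest pixel (origin at the image centre);
#' the footprint is the fixed plus shape or, in `"random"` shape mode, a
#' fresh random connected 5-pixel shape containing the centre pixel,
#' redrawn each frame to emulate the shape fluctuation of floppy
#' molecules.
#'
#' @param traj a `trajectory`.
#' @param config a [sim_config()].
#' @return an [occupancy_stack()] of planted footprints.
#' @export
rasterize_footprint <- function(traj, config) {
  n <- nrow(traj)
  H <- config$image_shape[1]; W <- config$image_shape[2]
  r0 <- H %/% 2L; c0 <- W %/% 2L
  psz <- config$pixel_size
  crow <- as.integer(round(traj$y / psz)) + r0
  ccol <- as.integer(round(traj$x / psz)) + c0
  fixed_off <- cross_offsets()
  footprints <- vector("list", n)
  for (i in seq_len(n)) {
    off <- if (config$shape_mode == "fixed") fixed_off
           else random_shape(config$n_pixels)
    fp <- cbind(row = crow[i] + off[, 1], col = ccol[i] + off[, 2])
    if (any(fp < 0L) || any(fp[, 1] >= H) || any(fp[, 2] >= W))
      stop(sprintf("frame %d: footprint outside image bounds; increase image_shape", i))
    footprints[[i]] <- fp
  }
  occupancy_stack(footprints, shape = c(H, W), dt = config$dt,
                  pixel_size = psz, n_pixels = config$n_pixels)
}

#' Split footprints in a fraction of frames
#'
#' Emulates the occasional defocusing of a floppy molecule, where the
#' 5-pixel footprint splits into two pixel groups.  In a uniformly chosen
#' subset of `floor(split_fraction * n)` frames, 2 of the 5 pixels are
#' displaced by `split_distance` pixels in both x and y (diagonally).
#'
#' @param occ an [occupancy_stack()].
#' @param split_fraction fraction of frames to modify.
#' @param split_distance displacement, pixels (>= 2 for a genuine split).
#' @return a modified `occupancy_stack`; modified frame indices in
#'   attribute `"split_frames"`.
#' @export
apply_splitting <- function(occ, split_fraction, split_distance = 2L) {
  stopifnot(split_fraction >= 0, split_fraction <= 1, split_distance >= 2L)
  n <- occ$n
  n_split <- floor(split_fraction * n)
  if (n_split == 0L) {
    attr(occ, "split_frames") <- integer(0)
    return(occ)
  }
  idx <- sort(sample.int(n, n_split))
  H <- occ$shape[1]; W <- occ$shape[2]
  for (i in idx) {
    fp <- occ$footprints[[i]]
    if (nrow(fp) < 3L) next
    moved <- sample.int(nrow(fp), 2L)
    fp[moved, 1] <- fp[moved, 1] + split_distance
    fp[moved, 2] <- fp[moved, 2] + split_distance
    if (any(fp < 0L) || any(fp[, 1] >= H) || any(fp[, 2] >= W))
      stop(sprintf("frame %d: displaced split group outside image bounds", i))
    occ$footprints[[i]] <- fp[!duplicated(fp), , drop = FALSE]
  }
  attr(occ, "split_frames") <- idx
  occ
}

#' Render an occupancy stack as a noisy image stack
#'
#' Each frame is i.i.d. Gaussian background noise (mean and s.d. from the
#' configuration) with the footprint pixels raised by `signal_amplitude`.
#' Negative noise excursions are clipped at zero.  With the default
#' amplitude of 8 background s.d., preprocessing at `k = 4` recovers the
#' planted footprints.
#'
#' @param occ an [occupancy_stack()].
#' @param config a [sim_config()].
#' @return an [image_stack()].
#' @export
render_stack <- function(occ, config) {
  H <- occ$shape[1]; W <- occ$shape[2]
  m <- config$background[1]; s <- config$background[2]
  frames <- lapply(occ$footprints, function(fp) {
    f <- matrix(stats::rnorm(H * W, mean = m, sd = s), nrow = H)
    if (nrow(fp) > 0L)
      f[cbind(fp[, 1] + 1L, fp[, 2] + 1L)] <-
        f[cbind(fp[, 1] + 1L, fp[, 2] + 1L)] + config$signal_amplitude
    pmax(f, 0)
  })
  image_stack(frames, dt = occ$dt, pixel_size = occ$pixel_size)
}

#' Simulate a batch of tracks and estimate D by the CA method
#'
#' Convenience driver for the validation experiments: simulates
#' `n_tracks` independent trajectories under one configuration,
#' rasterizes each (with optional footprint splitting) and runs the
#' cumulative-area estimator on the planted occupancy.  Per-track seeds
#' are derived deterministically from the master seed and the track
#' index, so any single track is reproducible in isolation.
#'
#' @param config a [sim_config()].
#' @param n_tracks number of independent tracks.
#' @param backward_correction passed to [ca_estimate()].
#' @return numeric vector of `n_tracks` CA diffusion estimates (um^2/s).
#' @export
simulate_ca_batch <- function(config, n_tracks = 100L,
                              backward_correction = TRUE) {
  vapply(seq_len(n_tracks), function(i) {
    set.seed((config$seed + 7919L * i) %% .Machine$integer.max)
    traj <- simulate_trajectory(config)
    occ <- rasterize_footprint(traj, config)
    if (config$split_fraction > 0)
      occ <- apply_splitting(occ, config$split_fraction,
                             config$split_distance)
    ca_estimate(occ, backward_correction = backward_correction)$D
  }, numeric(1))
}
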