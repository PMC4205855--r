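# Shared fixtures and independent oracles, all built in code.

# Independent brute-force oracle for cumulative areas: explicit set unions
# of (row, col) pairs, no key arithmetic shared with the implementation.
brute_cumulative <- function(footprints, backward = FALSE) {
  n <- length(footprints)
  idx <- if (backward) lapply(seq_len(n), function(i) i:n)
         else lapply(seq_len(n), function(i) 1:i)
  vapply(idx, function(js) {
    all_px <- do.call(rbind, footprints[js])
    if (is.null(all_px) || nrow(all_px) == 0L) return(0L)
    nrow(unique(as.data.frame(all_px)))
  }, integer(1))
}

# A horizontal 5-pixel row footprint at a given row offset.
row_footprint <- function(row, cols = 0:4) {
  cbind(row = rep(as.integer(row), length(cols)), col = as.integer(cols))
}

# Random footprint sequence on a small grid (possibly overlapping frames).
random_footprints <- function(n_frames, n_px = 5L, grid = 32L) {
  lapply(seq_len(n_frames), function(i) {
    r0 <- sample.int(grid - 4L, 1L) - 1L
    c0 <- sample.int(grid - 4L, 1L) - 1L
    k <- sample.int(n_px, 1L)
    cbind(row = r0 + sample.int(4L, k, replace = TRUE),
          col = c0 + sample.int(4L, k, replace = TRUE))
  })
}

make_occ <- function(footprints, shape = c(64L, 64L), dt = 0.0064,
                     pixel_size = 0.16, n_pixels = 5L) {
  footprints <- lapply(footprints, function(fp) fp[!duplicated(fp), , drop = FALSE])
  occupancy_stack(footprints, shape = shape, dt = dt,
                  pixel_size = pixel_size, n_pixels = n_pixels)
}

# Noise-free synthetic frame with a planted symmetric Gaussian spot.
gaussian_spot_frame <- function(nrow = 32L, ncol = 32L, r0, c0,
                                amplitude = 1000, sigma = 1.2,
                                offset = 100) {
  rr <- matrix(0:(nrow - 1L), nrow, ncol)
  cc <- matrix(0:(ncol - 1L), nrow, ncol, byrow = TRUE)
  offset + amplitude * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma^2))
}

# Image stack of a static 5-pixel cross over Gaussian background noise.
static_cross_stack <- function(n_frames = 30L, shape = c(64L, 64L),
                               m = 100, s = 10, amplitude = 8 * s,
                               dt = 0.0064, pixel_size = 0.16) {
  ctr <- shape %/% 2L
  fp <- cbind(row = ctr[1] + c(0L, -1L, 1L, 0L, 0L),
              col = ctr[2] + c(0L, 0L, 0L, -1L, 1L))
  frames <- lapply(seq_len(n_frames), function(i) {
    f <- matrix(rnorm(prod(shape), m, s), shape[1], shape[2])
    f[cbind(fp[, 1] + 1L, fp[, 2] + 1L)] <-
      f[cbind(fp[, 1] + 1L, fp[, 2] + 1L)] + amplitude
    pmax(f, 0)
  })
  list(stack = image_stack(frames, dt = dt, pixel_size = pixel_size),
       footprint = fp)
}
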