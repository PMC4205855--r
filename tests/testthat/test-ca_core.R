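test_that("worked example: shifted square footprints give M_fwd = [5, 8]", {
  F1 <- cbind(row = c(0L, 1L, 0L, 1L, 0L), col = c(0L, 0L, 1L, 1L, 2L))
  F2 <- F1; F2[, 1] <- F2[, 1] + 1L
  occ <- make_occ(list(F1, F2))
  expect_equal(cumulative_forward(occ), c(5L, 8L))
})

test_that("revisit example: backward pass rescues the masked increment", {
  F1 <- row_footprint(0)
  F2 <- row_footprint(1)
  F3 <- row_footprint(0)     # particle revisits frame 1's pixels
  occ <- make_occ(list(F1, F2, F3))
  M_fwd <- cumulative_forward(occ)
  M_bwd <- cumulative_backward(occ)
  expect_equal(M_fwd, c(5L, 10L, 10L))
  expect_equal(M_bwd, c(10L, 10L, 5L))
  ser <- increment_series(M_fwd, M_bwd)
  expect_equal(ser$dA, c(5L, 5L))
  expect_equal(ser$n_zero_both, 0L)
})

test_that("degenerate footprint sequences give the closed-form areas", {
  same <- replicate(6, row_footprint(3), simplify = FALSE)
  occ <- make_occ(same)
  expect_equal(cumulative_forward(occ), rep(5L, 6))
  expect_equal(cumulative_backward(occ), rep(5L, 6))
  ser <- increment_series(cumulative_forward(occ), cumulative_backward(occ))
  expect_equal(ser$dA, rep(0L, 5))
  expect_equal(ser$n_zero_both, 5L)   # static particle: all-zero increments

  disjoint <- lapply(0:5, row_footprint)
  occ2 <- make_occ(disjoint)
  expect_equal(cumulative_forward(occ2), 5L * (1:6))
  expect_equal(cumulative_backward(occ2), 5L * (6:1))
  ser2 <- increment_series(cumulative_forward(occ2),
                           cumulative_backward(occ2))
  expect_equal(ser2$dA, rep(5L, 5))   # monotone mover: forward never zero
})

test_that("cumulative areas match the brute-force set-union oracle", {
  set.seed(31)
  for (rep in 1:15) {
    fps <- random_footprints(sample(5:25, 1))
    occ <- make_occ(fps, shape = c(32L, 32L))
    expect_equal(cumulative_forward(occ), brute_cumulative(fps))
    expect_equal(cumulative_backward(occ),
                 brute_cumulative(fps, backward = TRUE))
  }
})

test_that("cumulative series invariants hold on random sequences", {
  set.seed(17)
  fps <- random_footprints(40)
  occ <- make_occ(fps, shape = c(32L, 32L))
  M_fwd <- cumulative_forward(occ)
  M_bwd <- cumulative_backward(occ)
  expect_true(all(diff(M_fwd) >= 0))
  expect_true(all(diff(M_bwd) <= 0))
  expect_equal(M_fwd[occ$n], M_bwd[1])    # both equal the total area
  ser <- increment_series(M_fwd, M_bwd)
  expect_true(all(ser$dA >= 0))
})

test_that("estimate_D applies the <dA>/(4 dt) conversion", {
  # single-increment toy: 3 px * 0.16^2 um^2 over 4 * 0.0064 s -> 3.0
  est <- suppressWarnings(
    estimate_D(3, dt = 0.0064, pixel_size = 0.16, min_increments = 1L))
  expect_equal(est$mean_dA, 0.0768)
  expect_equal(est$D, 3.0)
  expect_equal(est$method, "CA")

  est0 <- suppressWarnings(
    estimate_D(rep(0, 20), dt = 0.0064, pixel_size = 0.16))
  expect_equal(est0$D, 0)

  expect_error(estimate_D(rep(1, 5), 0.0064, 0.16), "too short")
})

test_that("increments adjacent to dropped frames are excluded", {
  dA <- c(rep(2, 10), 100, 100, rep(2, 10))   # frames 11..13 junk-adjacent
  est <- suppressWarnings(
    estimate_D(dA, dt = 0.0064, pixel_size = 0.16, dropped = 12L))
  expect_equal(est$n_increments, 20L)
  expect_equal(est$mean_dA, 2 * 0.16^2)
})

test_that("omitting the backward correction never raises the estimate", {
  set.seed(23)
  for (rep in 1:10) {
    cfg <- sim_config(D = runif(1, 0.5, 2), n_frames = 100L,
                      seed = 1000L + rep)
    traj <- simulate_trajectory(cfg)
    occ <- rasterize_footprint(traj, cfg)
    D_corr <- ca_estimate(occ)$D
    D_nocorr <- ca_estimate(occ, backward_correction = FALSE)$D
    expect_lte(D_nocorr, D_corr)
  }
})

test_that("frame-order reversal preserves the mean increment on revisit-free tracks", {
  disjoint <- lapply(seq(0, 18, by = 2), row_footprint)
  occ <- make_occ(disjoint)
  fwd_est <- suppressWarnings(ca_estimate(occ, min_increments = 1L))
  occ_rev <- make_occ(rev(disjoint))
  rev_est <- suppressWarnings(ca_estimate(occ_rev, min_increments = 1L))
  expect_equal(mean(fwd_est$series$dA), mean(rev_est$series$dA))
})

test_that("ca_pipeline estimates D end to end and enforces the quality gate", {
  set.seed(8)
  cfg <- sim_config(D = 1.0, n_frames = 60L, image_shape = c(96L, 96L),
                    seed = 8L)
  traj <- simulate_trajectory(cfg)
  occ <- rasterize_footprint(traj, cfg)
  stack <- render_stack(occ, cfg)
  est <- ca_pipeline(stack)
  expect_s3_class(est, "diffusion_estimate")
  expect_gt(est$D, 0.3)
  expect_lt(est$D, 2.5)

  # blank 10% of frames: dropped-frames gate must reject, force overrides
  blanked <- stack
  for (i in 1:6) blanked$frames[[i]] <- matrix(
    pmax(rnorm(96 * 96, 100, 10), 0), 96, 96)
  expect_error(ca_pipeline(blanked), "dropped frames ratio")
  expect_warning(est2 <- ca_pipeline(blanked, force = TRUE),
                 "quality gate")
  expect_s3_class(est2, "diffusion_estimate")
})

test_that("2-frame stacks fail estimate_D, not the superimposition", {
  occ <- make_occ(list(row_footprint(0), row_footprint(1)))
  expect_equal(cumulative_forward(occ), c(5L, 10L))
  expect_error(ca_estimate(occ), "too short")
})

test_that("mode curves separate directed, confined and random motion", {
  set.seed(12)
  cfg_dir <- sim_config(D = 1.0, n_frames = 100L, mode = "directed",
                        drift_velocity = 50, image_shape = c(512L, 512L))
  cls_dir <- classify_mode(mode_curve(rasterize_footprint(
    simulate_trajectory(cfg_dir), cfg_dir)))
  expect_gt(cls_dir$r2_linear, 0.99)
  expect_equal(cls_dir$mode, "directed")

  cfg_conf <- sim_config(D = 1.0, n_frames = 2000L, mode = "confined",
                         confinement_radius = 0.5)
  cls_conf <- classify_mode(mode_curve(rasterize_footprint(
    simulate_trajectory(cfg_conf), cfg_conf)))
  expect_lt(cls_conf$slope_ratio, 0.05)
  expect_equal(cls_conf$mode, "confined")

  cfg_rand <- sim_config(D = 1.0, n_frames = 100L, mode = "random")
  cls_rand <- classify_mode(mode_curve(rasterize_footprint(
    simulate_trajectory(cfg_rand), cfg_rand)))
  expect_equal(cls_rand$mode, "random")
})

test_that("sampling validity flags the displacement and pixel-count windows", {
  v1 <- check_sampling_validity(D = 1.0, dt = 0.0064, pixel_size = 0.16)
  expect_true(v1$valid)
  expect_equal(v1$rms_displacement, 0.16, tolerance = 1e-12)

  v2 <- check_sampling_validity(D = 0.05, dt = 0.0064, pixel_size = 0.16)
  expect_false(v2$valid)
  expect_equal(v2$displacement_pixels, sqrt(4 * 0.05 * 0.0064) / 0.16,
               tolerance = 1e-12)
  expect_match(v2$message, "longer frame interval|smaller pixels")

  v3 <- check_sampling_validity(D = 1.0, dt = 0.0064, pixel_size = 0.16,
                                n_pixels = 8L)
  expect_false(v3$valid)
  expect_match(v3$message, "pixel range")
})
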