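test_that("background fit recovers generator parameters and ignores signal outliers", {
  set.seed(42)
  frame <- matrix(rnorm(128 * 128, mean = 100, sd = 10), 128, 128)
  bg <- fit_background(frame)
  expect_equal(bg$m, 100, tolerance = 0.02)
  expect_equal(bg$s, 10, tolerance = 0.05)

  spiked <- frame
  spiked[cbind(60:64, 60:64)] <- spiked[cbind(60:64, 60:64)] + 100  # +10 s
  bg2 <- fit_background(spiked)
  expect_equal(bg2$m, bg$m, tolerance = 0.01)
  expect_equal(bg2$s, bg$s, tolerance = 0.02)

  expect_error(fit_background(matrix(5, 64, 64)), "degenerate")
  expect_error(fit_background(matrix(1, 5, 5)), "too small")
})

test_that("thresholding keeps exactly the pixels above m + k*s", {
  frame <- matrix(100, 20, 20)
  frame[3, 4] <- 150   # above 140
  frame[7, 9] <- 141
  frame[5, 5] <- 140   # exactly at threshold: excluded (strict >)
  px <- threshold_frame(frame, list(m = 100, s = 10), k = 4)
  expect_setequal(paste(px[, 1], px[, 2]), c("2 3", "6 8"))
  expect_equal(nrow(threshold_frame(matrix(100, 20, 20),
                                    list(m = 100, s = 10), k = 4)), 0L)
  expect_error(threshold_frame(frame, list(m = 100, s = 10), k = 0),
               "positive")
})

test_that("raising k never grows the thresholded set", {
  set.seed(7)
  frame <- matrix(rnorm(64 * 64, 100, 10), 64, 64)
  model <- list(m = 100, s = 10)
  sizes <- vapply(c(1, 2, 3, 4, 5),
                  function(k) nrow(threshold_frame(frame, model, k)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("noise removal drops exactly the 8-isolated pixels", {
  px <- rbind(c(0L, 0L), c(0L, 1L), c(5L, 5L))
  out <- remove_noise_pixels(px)
  expect_equal(out$n_removed, 1L)
  expect_setequal(paste(out$cleaned[, 1], out$cleaned[, 2]), c("0 0", "0 1"))

  plus <- cbind(c(5L, 4L, 6L, 5L, 5L), c(5L, 5L, 5L, 4L, 6L))
  out <- remove_noise_pixels(plus)
  expect_equal(out$n_removed, 0L)
  expect_equal(nrow(out$cleaned), 5L)

  expect_equal(remove_noise_pixels(plus[0, , drop = FALSE])$n_removed, 0L)

  # brute-force oracle on random sets: isolation by pairwise Chebyshev dist
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:25, 1)
    px <- unique(cbind(sample(0:11, n, TRUE), sample(0:11, n, TRUE)))
    keep_oracle <- vapply(seq_len(nrow(px)), function(i) {
      d <- pmax(abs(px[, 1] - px[i, 1]), abs(px[, 2] - px[i, 2]))
      any(d[-i] == 1) || any(d[-i] == 0)  # an 8-neighbour exists
    }, logical(1))
    out <- remove_noise_pixels(px)
    expect_equal(nrow(out$cleaned), sum(keep_oracle))
  }
})

test_that("footprint selection keeps the brightest pixels with deterministic ties", {
  frame <- matrix(0, 10, 10)
  px <- cbind(rep(2L, 8), 1:8)
  frame[3, 2:9] <- 141:148
  sel <- select_footprint(frame, px, n_pixels = 5L)
  expect_false(sel$short)
  expect_setequal(frame[cbind(sel$footprint[, 1] + 1L,
                              sel$footprint[, 2] + 1L)], 144:148)

  # short frame: everything returned and flagged
  sel3 <- select_footprint(frame, px[1:3, ], n_pixels = 5L)
  expect_true(sel3$short)
  expect_equal(nrow(sel3$footprint), 3L)

  # tie at the cutoff: lexicographically earliest pixel wins, repeatably
  tie_frame <- matrix(0, 10, 10)
  tie_px <- cbind(c(0L, 1L, 2L, 3L, 4L, 5L), rep(0L, 6))
  tie_frame[cbind(tie_px[, 1] + 1L, tie_px[, 2] + 1L)] <-
    c(150, 150, 150, 150, 149, 149)
  s1 <- select_footprint(tie_frame, tie_px, 5L)
  s2 <- select_footprint(tie_frame, tie_px, 5L)
  expect_identical(s1$footprint, s2$footprint)
  expect_true(all(s1$footprint[, 1] != 5L))  # (4,0) beats (5,0) at the tie
})

test_that("quality gate applies the 20% and 1% bounds inclusively", {
  fp <- function(empty) if (empty) matrix(integer(0), 0, 2) else
    cbind(0L, 0:4)
  fps <- lapply(seq_len(100), function(i) fp(i <= 2))
  q <- assess_quality(fps, noise_counts = rep(0L, 100),
                      raw_counts = rep(5L, 100))
  expect_equal(q$dropped_frames_ratio, 0.02)
  expect_false(q$accepted)

  fps10 <- lapply(1:10, function(i) fp(FALSE))
  q2 <- assess_quality(fps10, noise_counts = c(10L, rep(0L, 9)),
                       raw_counts = c(14L, rep(4L, 9)))
  expect_equal(q2$internal_noise_ratio, 0.20)
  expect_true(q2$accepted)

  q3 <- assess_quality(fps10, rep(0L, 10), rep(5L, 10))
  expect_equal(q3$internal_noise_ratio, 0)
  expect_equal(q3$dropped_frames_ratio, 0)
  expect_true(q3$accepted)

  expect_error(assess_quality(fps10, rep(0L, 10), rep(0L, 10)), "no signal")
})

test_that("preprocessing recovers planted footprints frame by frame", {
  set.seed(99)
  fx <- static_cross_stack(n_frames = 20L)
  occ <- preprocess_stack(fx$stack)
  expect_s3_class(occ, "occupancy_stack")
  expect_equal(occ$n, 20L)
  hits <- vapply(occ$footprints, function(fp)
    setequal(paste(fp[, 1], fp[, 2]),
             paste(fx$footprint[, 1], fx$footprint[, 2])), logical(1))
  expect_gte(mean(hits), 0.99)
  expect_true(occ$quality$accepted)

  # footprint is always a subset of the thresholded set
  for (i in c(1L, 10L)) {
    bg <- fit_background(fx$stack$frames[[i]])
    thr <- threshold_frame(fx$stack$frames[[i]], bg)
    fp <- occ$footprints[[i]]
    expect_true(all(paste(fp[, 1], fp[, 2]) %in% paste(thr[, 1], thr[, 2])))
  }
})

test_that("simulated render -> preprocess round trip recovers footprints", {
  set.seed(5)
  cfg <- sim_config(D = 1.0, n_frames = 40L, image_shape = c(64L, 64L),
                    seed = 5L)
  traj <- simulate_trajectory(cfg)
  occ <- rasterize_footprint(traj, cfg)
  stack <- render_stack(occ, cfg)
  rec <- preprocess_stack(stack)
  hits <- vapply(seq_len(occ$n), function(i)
    setequal(paste(occ$footprints[[i]][, 1], occ$footprints[[i]][, 2]),
             paste(rec$footprints[[i]][, 1], rec$footprints[[i]][, 2])),
    logical(1))
  expect_gte(mean(hits), 0.99)
})
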