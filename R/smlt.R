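# SMLT-MSD baseline: 2D Gaussian localization of the molecule in each
# frame, trajectory assembly, mean-square-displacement analysis, and the
# theoretical statistical distribution of single-trajectory D estimates.

#' Localize a molecule by 2D Gaussian fitting
#'
#' Fits an elliptical 2D Gaussian (amplitude, centre, per-axis widths,
#' offset) to a window around the brightest cleaned above-threshold pixel.
#' The localization is gated: the fit must converge, the centre must lie
#' inside the window, and both widths must be in `[0.5, 3]` pixel s.d. --
#' gates that make localization failures on floppy or split molecules
#' explicit and countable.
#'
#' @param frame numeric matrix.
#' @param model background model from [fit_background()].
#' @param pixel_size pixel size, um.
#' @param k threshold multiplier for candidate pixels.
#' @param window odd window edge length in pixels (default 7).
#' @return list with `x`, `y` (um, x = col*pixel_size, y = row*pixel_size)
#'   and `success`.
#' @export
localize_frame <- function(frame, model, pixel_size, k = 4, window = 7L) {
  px <- threshold_frame(frame, model, k = k)
  px <- remove_noise_pixels(px)$cleaned
  if (nrow(px) == 0L)
    return(list(x = NA_real_, y = NA_real_, success = FALSE))
  inten <- frame[cbind(px[, 1] + 1L, px[, 2] + 1L)]
  ctr <- unname(px[which.max(inten), ])
  h <- window %/% 2L
  H <- nrow(frame); W <- ncol(frame)
  r1 <- max(ctr[1] - h, 0L); r2 <- min(ctr[1] + h, H - 1L)
  c1 <- max(ctr[2] - h, 0L); c2 <- min(ctr[2] + h, W - 1L)
  sub <- frame[(r1:r2) + 1L, (c1:c2) + 1L, drop = FALSE]
  d <- expand.grid(row = r1:r2, col = c1:c2)
  d$z <- as.numeric(sub)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + a * exp(-((row - r0)^2 / (2 * sr^2) +
                        (col - c0)^2 / (2 * sc^2))),
      data = d,
      start = list(b = model$m, a = max(d$z) - model$m,
                   r0 = ctr[1], c0 = ctr[2], sr = 1, sc = 1),
      lower = c(-Inf, 0, r1, c1, 0.1, 0.1),
      upper = c(Inf, Inf, r2, c2, 10, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(x = NA_real_, y = NA_real_, success = FALSE))
  cf <- stats::coef(fit)
  inside <- cf["r0"] > r1 && cf["r0"] < r2 && cf["c0"] > c1 && cf["c0"] < c2
  widths_ok <- all(c(cf["sr"], cf["sc"]) >= 0.5) &&
    all(c(cf["sr"], cf["sc"]) <= 3)
  if (!inside || !widths_ok)
    return(list(x = NA_real_, y = NA_real_, success = FALSE))
  list(x = unname(cf["c0"]) * pixel_size, y = unname(cf["r0"]) * pixel_size,
       success = TRUE)
}

#' Assemble a trajectory from per-frame localizations
#'
#' Single-molecule stacks contain one molecule, so linking is
#' concatenation with gap handling: failed localizations are retained as
#' invalid frames, and the trajectory is truncated at the first run of
#' invalid frames longer than 1% of the stack (at least one frame) --
#' beyond that the identity of the molecule can no longer be assumed.
#'
#' @param locs list of per-frame localizations from [localize_frame()].
#' @param dt frame interval, s.
#' @return a `trajectory` data frame with `t`, `x`, `y`, `valid`.
#' @export
build_trajectory <- function(locs, dt) {
  n <- length(locs)
  valid <- vapply(locs, function(l) isTRUE(l$success), logical(1))
  max_gap <- max(1L, floor(0.01 * n))
  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  bad <- which(r$values & r$lengths > max_gap)
  keep <- if (length(bad)) ends[bad[1]] - r$lengths[bad[1]] else n
  if (sum(valid[seq_len(keep)]) < 10L)
    stop("fewer than 10 valid localizations before the first long gap")
  traj <- data.frame(
    t = (seq_len(keep) - 1) * dt,
    x = vapply(locs[seq_len(keep)], function(l) l$x %||% NA_real_, 0),
    y = vapply(locs[seq_len(keep)], function(l) l$y %||% NA_real_, 0),
    valid = valid[seq_len(keep)])
  attr(traj, "dt") <- dt
  class(traj) <- c("trajectory", "data.frame")
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean square displacement of a trajectory
#'
#' `MSD(n dt)` is the mean over all valid position pairs separated by
#' exactly `n` frames of `(x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2`.  For 2D
#' Brownian motion `MSD(n dt) = 4 D n dt`.
#'
#' @param traj a `trajectory` (>= 10 valid points).
#' @param max_lag_fraction largest lag as a fraction of trajectory length.
#' @return object of class `msd_curve`: data frame with `lag` (s), `msd`
#'   (um^2) and `count` (pairs per lag); attribute `dt`.
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25) {
  ok <- traj$valid
  if (sum(ok) < 10L) stop("need at least 10 valid points for MSD")
  n <- nrow(traj)
  dt <- attr(traj, "dt")
  max_lag <- max(1L, floor(max_lag_fraction * n))
  res <- vapply(seq_len(max_lag), function(l) {
    i <- seq_len(n - l)
    use <- ok[i] & ok[i + l]
    if (!any(use)) return(c(NA_real_, 0))
    d2 <- (traj$x[i + l] - traj$x[i])^2 + (traj$y[i + l] - traj$y[i])^2
    c(mean(d2[use]), sum(use))
  }, numeric(2))
  out <- data.frame(lag = seq_len(max_lag) * dt, msd = res[1, ],
                    count = as.integer(res[2, ]))
  attr(out, "dt") <- dt
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Diffusion coefficient from the MSD slope
#'
#' Unweighted linear fit with free intercept over the first `n_fit_points`
#' lags; `D = slope / 4`.  The free intercept absorbs the static offset
#' from localization noise.  A negative slope is clamped to `D = 0` with a
#' warning.
#'
#' @param curve an [compute_msd()] result with at least `n_fit_points` lags.
#' @param n_fit_points number of leading lags to fit (default 4).
#' @return a `diffusion_estimate` with `method = "SMLT-MSD"`.
#' @export
fit_msd_D <- function(curve, n_fit_points = 4L) {
  d <- curve[seq_len(n_fit_points), ]
  if (nrow(d) < n_fit_points || anyNA(d$msd))
    stop("MSD curve has fewer usable lags than 'n_fit_points'")
  fit <- stats::lm(msd ~ lag, data = d)
  slope <- unname(stats::coef(fit)[2])
  D <- slope / 4
  if (D < 0) {
    warning("negative MSD slope; clamping D to 0")
    D <- 0
  }
  structure(
    list(D = D, mean_dA = NA_real_, n_increments = nrow(d),
         method = "SMLT-MSD", intercept = unname(stats::coef(fit)[1])),
    class = "diffusion_estimate")
}

#' SMLT-MSD pipeline on an image stack
#'
#' Localizes the molecule in every frame, assembles the trajectory,
#' computes the MSD and fits D from its slope.
#'
#' @param stack an [image_stack()].
#' @param k threshold multiplier.
#' @param n_fit_points leading MSD lags used in the fit.
#' @return a `diffusion_estimate` with the trajectory attached.
#' @export
smlt_pipeline <- function(stack, k = 4, n_fit_points = 4L) {
  locs <- lapply(seq_len(stack$n), function(i) {
    bg <- fit_background(stack$frames[[i]])
    localize_frame(stack$frames[[i]], bg, pixel_size = stack$pixel_size,
                   k = k)
  })
  traj <- build_trajectory(locs, dt = stack$dt)
  est <- fit_msd_D(compute_msd(traj), n_fit_points = n_fit_points)
  est$trajectory <- traj
  est
}

#' Theoretical distribution of single-trajectory D estimates
#'
#' In a homogeneous environment, a diffusion coefficient estimated from
#' `N` independent displacement pairs of a trajectory with true mean `D0`
#' follows the gamma form
#' `p(D) = (N/D0)^N * D^(N-1) * exp(-N D / D0) / (N-1)!`,
#' i.e. a gamma distribution with shape `N` and mean `D0` (s.d.
#' `D0/sqrt(N)`).  The statistical width of an SMLT-MSD histogram is
#' compared against this density.
#'
#' @param D quantiles, um^2/s (>= 0).
#' @param N number of independent displacement pairs (integer >= 1).
#' @param D0 true mean diffusion coefficient, um^2/s.
#' @return density values at `D`.
#' @export
theoretical_pD <- function(D, N, D0) {
  if (N < 1 || N != round(N)) stop("'N' must be a positive integer")
  if (D0 <= 0) stop("'D0' must be positive")
  if (any(D < 0)) stop("'D' must be nonnegative")
  stats::dgamma(D, shape = N, rate = N / D0)
}
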