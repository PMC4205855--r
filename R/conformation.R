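# Conformational dynamics: per-frame occupied area under an extended upper
# pixel threshold, autocorrelation of the area fluctuation, and
# single-exponential relaxation-time fitting.

#' Per-frame occupied-area series
#'
#' For a flexible molecule (e.g. long DNA) the occupied area fluctuates
#' with conformation.  Each frame is background-thresholded and denoised
#' exactly as in [preprocess_stack()], then up to `upper_threshold`
#' brightest pixels are retained (rather than the 5-pixel diffusion
#' footprint), so the full molecular shape is captured.  With
#' `upper_threshold` equal to the diffusion footprint size this reduces to
#' the CA footprint areas.
#'
#' @param stack an [image_stack()].
#' @param upper_threshold pixel-count cap (sane range 10-200; typically
#'   40-60, see [choose_upper_threshold()]).
#' @param k background threshold multiplier.
#' @return object of class `area_series`: list with `A` (um^2 per frame),
#'   `n_px` (retained pixel counts), `dt`, `upper_threshold`.
#' @export
area_series <- function(stack, upper_threshold, k = 4) {
  stopifnot(inherits(stack, "image_stack"))
  if (upper_threshold < 1 || upper_threshold > 200)
    stop("'upper_threshold' outside the sane range 1-200 pixels")
  if (upper_threshold < 10)
    warning("'upper_threshold' below 10 pixels reduces to the diffusion footprint; conformational signal will be limited")
  n_px <- integer(stack$n)
  for (i in seq_len(stack$n)) {
    frame <- stack$frames[[i]]
    bg <- fit_background(frame)
    px <- threshold_frame(frame, bg, k = k)
    cl <- remove_noise_pixels(px)$cleaned
    sel <- select_footprint(frame, cl, n_pixels = upper_threshold)
    n_px[i] <- nrow(sel$footprint)
  }
  structure(
    list(A = n_px * stack$pixel_size^2, n_px = n_px, dt = stack$dt,
         upper_threshold = upper_threshold),
    class = "area_series")
}

#' Choose the upper pixel threshold for area analysis
#'
#' The cap is the largest number of cleaned above-threshold pixels seen in
#' any frame of the recording -- representing the fully extended molecule
#' -- clipped to the 40-60 pixel working range.
#'
#' @param stack an [image_stack()].
#' @param k background threshold multiplier.
#' @param range clipping range in pixels.
#' @return upper threshold in pixels.
#' @export
choose_upper_threshold <- function(stack, k = 4, range = c(40L, 60L)) {
  counts <- vapply(seq_len(stack$n), function(i) {
    frame <- stack$frames[[i]]
    bg <- fit_background(frame)
    nrow(remove_noise_pixels(threshold_frame(frame, bg, k = k))$cleaned)
  }, integer(1))
  mx <- max(counts)
  if (mx < range[1])
    warning(sprintf("largest cleaned pixel count (%d) below %d; clipping up",
                    mx, range[1]))
  min(max(mx, range[1]), range[2])
}

#' Autocorrelation of the occupied-area fluctuation
#'
#' `G(tau) = <dA(t) dA(t+tau)> / <dA^2>` with `dA = A - mean(A)`, using
#' the biased normalization (divide by `n` at every lag) for variance
#' stability at long lags.  Lags run from 0 to `n/4` frames; `G(0) = 1`
#' exactly after normalization.
#'
#' @param series an [area_series()] or a numeric vector of areas (then
#'   `dt` must be given).
#' @param dt frame interval, s (taken from `series` when available).
#' @param max_lag_fraction lag range as a fraction of the series length.
#' @return data frame with `lag` (s) and `G`.
#' @export
autocorrelate <- function(series, dt = NULL, max_lag_fraction = 0.25) {
  if (inherits(series, "area_series")) {
    A <- series$A
    dt <- series$dt
  } else {
    A <- as.numeric(series)
    if (is.null(dt)) stop("'dt' required when passing a bare numeric series")
  }
  n <- length(A)
  if (n < 50L) stop("need at least 50 frames for autocorrelation analysis")
  dA <- A - mean(A)
  denom <- sum(dA^2) / n
  if (denom == 0)
    stop("zero area variance: rigid object, no conformational signal")
  max_lag <- floor(n * max_lag_fraction)
  G <- vapply(0:max_lag, function(l)
    sum(dA[seq_len(n - l)] * dA[seq_len(n - l) + l]) / n / denom, numeric(1))
  data.frame(lag = (0:max_lag) * dt, G = G)
}

#' Fit a single-exponential relaxation time
#'
#' Least-squares fit of `G(tau) = a * exp(-tau / tau_R)` over lags
#' `tau >= 1` frame (lag 0 is excluded; no additive offset).  The fit is
#' flagged unreliable if it fails to converge or the fitted `tau_R` falls
#' outside the fitted lag range.
#'
#' @param acf_df data frame with `lag` (s) and `G`, e.g. from
#'   [autocorrelate()]; at least 10 positive-lag points.
#' @return object of class `relaxation_result`: list with `tau_R` (s),
#'   `amplitude`, `fit_ok` and the input curve.
#' @export
fit_relaxation <- function(acf_df) {
  d <- acf_df[acf_df$lag > 0, ]
  if (nrow(d) < 10L) stop("need at least 10 positive-lag points for the fit")
  tau0 <- max(d$lag[which(d$G < exp(-1))[1]], d$lag[2], na.rm = TRUE)
  fit <- tryCatch(
    minpack.lm::nlsLM(G ~ a * exp(-lag / tauR), data = d,
                      start = list(a = max(d$G[1], 0.5), tauR = tau0),
                      lower = c(0, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(tau_R = NA_real_, amplitude = NA_real_,
                          fit_ok = FALSE, curve = acf_df),
                     class = "relaxation_result"))
  }
  cf <- stats::coef(fit)
  tau_R <- unname(cf["tauR"])
  ok <- is.finite(tau_R) && tau_R > 0 && tau_R <= max(d$lag) * 4
  structure(list(tau_R = tau_R, amplitude = unname(cf["a"]),
                 fit_ok = ok, curve = acf_df),
            class = "relaxation_result")
}

#' @export
print.relaxation_result <- function(x, ...) {
  if (x$fit_ok)
    cat(sprintf("relaxation fit: tau_R = %.4g s (amplitude %.3g)\n",
                x$tau_R, x$amplitude))
  else cat("relaxation fit: did not converge (fit_ok = FALSE)\n")
  invisible(x)
}

#' Relaxation analysis of an image stack
#'
#' Composition: occupied-area series under the (auto-chosen or given)
#' upper threshold, autocorrelation of the fluctuation, exponential fit.
#' When several molecules are analysed, average their `G` curves first and
#' fit once (see [average_acf()]).
#'
#' @param stack an [image_stack()].
#' @param upper_threshold pixel cap, or `NULL` to choose automatically.
#' @param k background threshold multiplier.
#' @return a `relaxation_result` with the `area_series` attached.
#' @export
relaxation_analysis <- function(stack, upper_threshold = NULL, k = 4) {
  if (is.null(upper_threshold))
    upper_threshold <- choose_upper_threshold(stack, k = k)
  ser <- area_series(stack, upper_threshold, k = k)
  res <- fit_relaxation(autocorrelate(ser))
  res$area_series <- ser
  res
}

#' Average autocorrelation curves over molecules
#'
#' Population relaxation times are obtained by averaging the normalized
#' `G(tau)` curves of many molecules on a common lag grid and fitting the
#' averaged curve once.
#'
#' @param acf_list list of data frames with `lag` and `G` (equal lag grids
#'   up to the shortest).
#' @return data frame with `lag` and mean `G`.
#' @export
average_acf <- function(acf_list) {
  stopifnot(length(acf_list) >= 1L)
  len <- min(vapply(acf_list, nrow, 0L))
  G <- rowMeans(vapply(acf_list, function(d) d$G[seq_len(len)],
                       numeric(len)))
  data.frame(lag = acf_list[[1]]$lag[seq_len(len)], G = G)
}

#' AR(1) surrogate for an exponentially correlated area series
#'
#' Generates a stationary Gaussian series whose autocorrelation decays as
#' `exp(-lag/tau)`: an order-1 autoregressive process with coefficient
#' `phi = exp(-dt/tau)`.  Used as ground truth for relaxation-time
#' recovery tests -- it mimics the area fluctuation statistics of a
#' flexible chain without simulating polymer dynamics.
#'
#' @param n series length.
#' @param tau correlation time, s.
#' @param dt sampling interval, s.
#' @param mean,sd stationary mean and s.d. of the series.
#' @return numeric vector of length `n`.
#' @export
ar1_area_series <- function(n, tau, dt, mean = 1, sd = 0.2) {
  phi <- exp(-dt / tau)
  x <- numeric(n)
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
  x[1] <- stats::rnorm(1, sd = sd)
  for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i]
  x + mean
}
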