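# Population statistics over many molecules: Gaussian fits to frequency
# distributions of D, accuracy-band checks, and the Stokes-Einstein
# reference value.

#' Gaussian fit to a distribution of diffusion coefficients
#'
#' Histograms the per-molecule estimates (Freedman-Diaconis bins by
#' default) and fits a single Gaussian to the frequency distribution by
#' unweighted least squares, reporting the fitted peak and s.d. alongside
#' the arithmetic mean and sample s.d. (both are always reported: frequency
#' histograms are summarized by the fitted peak, tabulated values by the
#' arithmetic mean).  If the fit fails, the result falls back to
#' mean +/- s.d. with `fit_ok = FALSE`.
#'
#' @param estimates numeric vector of D values (>= 10).
#' @param breaks passed to [graphics::hist()]; default Freedman-Diaconis.
#' @return object of class `distribution_fit`: list with `peak`, `sigma_D`,
#'   `relative_sigma`, `mean`, `sd`, `n_molecules`, `fit_ok`.
#' @export
fit_D_distribution <- function(estimates, breaks = "FD") {
  estimates <- estimates[is.finite(estimates)]
  if (length(estimates) < 10L)
    stop("need at least 10 estimates for a distribution fit")
  mu <- mean(estimates)
  sdev <- stats::sd(estimates)
  fit_ok <- FALSE
  peak <- mu
  sigma <- sdev
  if (sdev > 0) {
    h <- graphics::hist(estimates, breaks = breaks, plot = FALSE)
    df <- data.frame(x = h$mids, y = h$counts)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-(x - m)^2 / (2 * s^2)), data = df,
                        start = list(a = max(df$y), m = mu, s = sdev),
                        lower = c(0, -Inf, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      peak <- unname(cf["m"])
      sigma <- abs(unname(cf["s"]))
      fit_ok <- TRUE
    }
  }
  structure(
    list(peak = peak, sigma_D = sigma,
         relative_sigma = sigma / peak, mean = mu, sd = sdev,
         n_molecules = length(estimates), fit_ok = fit_ok),
    class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf(
    "distribution_fit (n = %d): peak %.4g +/- %.3g um^2/s (Gaussian%s); mean %.4g +/- %.3g\n",
    x$n_molecules, x$peak, x$sigma_D,
    if (x$fit_ok) "" else " fit failed, fallback", x$mean, x$sd))
  invisible(x)
}

#' Accuracy-band check against a preset diffusion coefficient
#'
#' Percent deviation of an estimate (or fitted peak) from the preset value,
#' flagged against an accuracy band of +/- `band_fraction` (default the
#' +/-20% threshold used to validate simulated estimates).
#'
#' @param estimate a number or a `distribution_fit` (its `peak` is used).
#' @param D_preset true simulated value, um^2/s (> 0).
#' @param band_fraction half-width of the band as a fraction.
#' @return list with `deviation_pct` and `within_band`.
#' @export
accuracy_check <- function(estimate, D_preset, band_fraction = 0.20) {
  stopifnot(D_preset > 0)
  if (inherits(estimate, "distribution_fit")) estimate <- estimate$peak
  dev <- abs(estimate - D_preset) / D_preset * 100
  list(deviation_pct = dev, within_band = dev <= band_fraction * 100)
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB T / (6 pi eta r)` for a sphere of radius `r` in a fluid of
#' viscosity `eta`, returned in um^2/s.
#'
#' @param radius hydrodynamic radius, um.
#' @param temperature absolute temperature, K.
#' @param viscosity dynamic viscosity, Pa s (water at 20 C: 1.002e-3).
#' @return D in um^2/s.
#' @export
stokes_einstein_D <- function(radius, temperature = 293.15,
                              viscosity = 1.002e-3) {
  stopifnot(radius > 0, temperature > 0, viscosity > 0)
  kB <- 1.380649e-23                      # J/K
  D_m2s <- kB * temperature / (6 * pi * viscosity * radius * 1e-6)
  D_m2s * 1e12
}
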