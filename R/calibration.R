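# Sensitivity fitting, baseline noise, limit of detection, the
# Gaussian-fit theoretical gamma sensitivity, and concentration-LOD
# extrapolation.

#' Ordinary least-squares sensitivity fit
#'
#' Fits `y = slope * x + intercept` by unweighted OLS, the convention used
#' for both the spectral-shift calibration (y in nm) and the gamma
#' calibration (y in a.u.); the slope inherits the units of `y` per RIU.
#'
#' @param x Refractive indices (RIU), at least two distinct values.
#' @param y Responses (dip wavelengths in nm, or gamma in a.u.).
#' @return List with `slope`, `intercept`, `r_squared`, `slope_se`, `n`.
#' @export
fit_sensitivity <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L) stop("need at least two distinct x values")
  fit <- stats::lm(y ~ x)
  # collinear calibration data is a legitimate input; summary.lm warns on it
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       slope_se = sm$coefficients[2L, 2L],
       n = length(x))
}

#' Baseline noise as a windowed sample standard deviation
#'
#' @param series Numeric vector, or a `gamma_series` (its `gamma_mean`
#'   column is used).
#' @param window Optional index range `c(first, last)` within the series.
#' @return Sample standard deviation (n - 1 denominator).
#' @export
baseline_noise <- function(series, window = NULL) {
  v <- if (inherits(series, "gamma_series")) series$gamma_mean else series
  stopifnot(is.numeric(v))
  if (!is.null(window)) {
    if (window[1L] < 1L || window[2L] > length(v) || window[1L] >= window[2L])
      stop("window outside the series")
    v <- v[window[1L]:window[2L]]
  }
  if (length(v) < 2L) stop("need at least two samples")
  stats::sd(v)
}

#' Refractive-index limit of detection
#'
#' `LOD = noise / |sensitivity|`. (The accompanying text convention of a
#' "ratio of sensitivity to noise" is inverted with respect to the printed
#' values; the arithmetic here follows the numbers.)
#'
#' @param noise Baseline noise in the units of the response (nm or a.u.).
#' @param sensitivity Response slope per RIU (non-zero).
#' @return Detection limit in RIU.
#' @examples
#' detection_limit(0.46, 244.7)      # spectral-shift mode
#' detection_limit(1.23e-4, 2.25)    # gamma mode
#' @export
detection_limit <- function(noise, sensitivity) {
  if (!is.finite(sensitivity) || sensitivity == 0) stop("zero sensitivity")
  if (noise < 0) stop("`noise` must be >= 0")
  noise / abs(sensitivity)
}

#' Bundle a calibration outcome
#'
#' @param mode `"spectral_shift"` or `"gamma"`.
#' @param sensitivity,intercept,r_squared OLS fit results.
#' @param baseline_noise Noise in response units.
#' @param response_unit Unit string for the response (`"nm"` or `"a.u."`).
#' @return A `calibration_result` with `lod = baseline_noise /
#'   |sensitivity|`.
#' @export
calibration_result <- function(mode = c("spectral_shift", "gamma"),
                               sensitivity, intercept = NA_real_,
                               r_squared = NA_real_, baseline_noise,
                               response_unit = c("nm", "a.u.")) {
  mode <- match.arg(mode)
  response_unit <- match.arg(response_unit)
  structure(
    list(mode = mode, sensitivity = sensitivity, intercept = intercept,
         r_squared = r_squared, baseline_noise = baseline_noise,
         lod = detection_limit(baseline_noise, sensitivity),
         sensitivity_unit = paste0(response_unit, "/RIU"),
         noise_unit = response_unit),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result: %s>\n", x$mode))
  cat(sprintf("  sensitivity  %.6g %s (R^2 = %.4f)\n", x$sensitivity,
              x$sensitivity_unit, x$r_squared))
  cat(sprintf("  noise        %.3g %s\n", x$baseline_noise, x$noise_unit))
  cat(sprintf("  LOD          %.3g RIU\n", x$lod))
  invisible(x)
}

#' Theoretical gamma sensitivity from a Gaussian-fitted dip
#'
#' The model-based counterpart of the measured gamma calibration: red-shift
#' the fitted Gaussian dip by `S_lambda * (n - n0)` over a refractive-index
#' interval, push each shifted spectrum through the two filter passbands
#' to get `I_A` and `I_AB`, evaluate gamma, and take the OLS slope of gamma
#' versus n. This converts the dip's wavelength response into the
#' contrast-statistic response without any detector or mosaic effects.
#'
#' @param filter_A,filter_AB Passband spectra (A nested in AB).
#' @param dip A [dip_model()]; its centre is interpreted at `n_range[1]`
#'   when the model carries no reference index.
#' @param sensitivity_nm_riu Wavelength sensitivity used for the
#'   conversion; defaults to the dip model's own slope.
#' @param n_range Refractive-index interval.
#' @param n_points Number of evaluation points.
#' @param illumination Optional illumination spectrum.
#' @return List with `slope` (a.u./RIU), `intercept`, `r_squared`,
#'   `gamma` (data frame of n and gamma) and `dip_left_band` (TRUE, with a
#'   warning, if the shifted dip centre exits the wide passband).
#' @export
theoretical_gamma_sensitivity <- function(filter_A, filter_AB, dip,
                                          sensitivity_nm_riu = NULL,
                                          n_range = c(1.333, 1.3495),
                                          n_points = 30,
                                          illumination = NULL) {
  assert_nested_filters(filter_A, filter_AB)
  stopifnot(inherits(dip, "dip_model"))
  if (is.null(sensitivity_nm_riu)) sensitivity_nm_riu <- dip$sensitivity_nm_riu
  if (!is.finite(sensitivity_nm_riu)) stop("a finite wavelength sensitivity is required")
  n0 <- if (is.finite(dip$n0)) dip$n0 else n_range[1L]
  ns <- seq(n_range[1L], n_range[2L], length.out = n_points)
  centers <- dip$lambda0 + sensitivity_nm_riu * (ns - n0)
  bl <- band_limits(filter_AB)
  left_band <- any(centers < bl[1L] | centers > bl[2L])
  if (left_band)
    warning("dip centre leaves the wide passband within the scanned index range")
  grid <- filter_A$grid
  gam <- vapply(seq_along(ns), function(k) {
    r <- dip$baseline - dip$depth *
      exp(-(grid$values - centers[k])^2 / (2 * dip$width_nm^2))
    refl <- new_spectrum(grid, r)
    gamma_value(band_intensity(refl, filter_A, illumination),
                band_intensity(refl, filter_AB, illumination))
  }, numeric(1L))
  fit <- fit_sensitivity(ns, gam)
  list(slope = fit$slope, intercept = fit$intercept,
       r_squared = fit$r_squared,
       gamma = data.frame(n = ns, gamma = gam),
       dip_left_band = left_band)
}

#' Concentration limit of detection from post-wash responses
#'
#' Fits the post-wash gamma change against analyte concentration —
#' `delta_gamma = a * log10(C) + b` by default, or a through-origin linear
#' response — and returns the concentration at which the response equals
#' `k` times the baseline noise (the k-sigma convention, k = 3 by
#' default). Results below the lowest measured concentration are flagged
#' as extrapolated.
#'
#' @param concentrations Analyte concentrations, ug/mL, strictly
#'   increasing and positive.
#' @param delta_gamma Post-wash gamma differences (a.u.), positive.
#' @param noise Baseline gamma noise (a.u.).
#' @param k Noise multiplier defining the detection threshold.
#' @param mode `"log10"` (default) or `"linear"` response model.
#' @return List with `c_lod` (ug/mL), `slope`, `extrapolated`.
#' @export
concentration_lod <- function(concentrations, delta_gamma, noise, k = 3,
                              mode = c("log10", "linear")) {
  mode <- match.arg(mode)
  stopifnot(length(concentrations) == length(delta_gamma))
  if (length(concentrations) < 2L) stop("need at least two concentration points")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (any(delta_gamma <= 0)) stop("responses must be positive")
  if (noise < 0) stop("`noise` must be >= 0")
  if (mode == "linear") {
    fit <- stats::lm(delta_gamma ~ 0 + concentrations)
    a <- unname(stats::coef(fit)[1L])
    if (a <= 0) stop("non-positive response slope")
    c_lod <- k * noise / a
  } else {
    x <- log10(concentrations)
    fit <- stats::lm(delta_gamma ~ x)
    a <- unname(stats::coef(fit)[2L])
    if (a <= 0) stop("non-positive response slope")
    c_lod <- 10^((k * noise - unname(stats::coef(fit)[1L])) / a)
  }
  list(c_lod = c_lod, slope = a, k = k, mode = mode,
       extrapolated = c_lod < concentrations[1L])
}

#' Simulated spectrometer readout of the resonance dip
#'
#' Companion measurement channel to the imaging pipeline: samples the SPR
#' reflectance on a coarse spectrometer grid, adds intensity noise, and
#' records the in-band minimum per acquisition — the raw dip-tracking
#' method. The per-spectrum scatter of these raw minima is the
#' spectral-mode baseline noise.
#'
#' @param protocol An [ri_protocol()].
#' @param dip A [dip_model()].
#' @param period_s Seconds between spectra (default 60 s: ten per
#'   ten-minute state).
#' @param step_nm Spectrometer sampling pitch, nm.
#' @param noise_sigma Additive intensity noise (relative reflectance
#'   units) per sample.
#' @param band Dip search band, `c(cut_on, cut_off)` nm.
#' @param seed RNG seed.
#' @return Data frame: `time`, `n`, `lambda_raw` (argmin dip estimate) and
#'   the per-time noisy spectra as an attribute `"spectra"` (matrix,
#'   wavelengths x times) with grid attribute `"grid"`.
#' @export
simulate_dip_readout <- function(protocol, dip, period_s = 60, step_nm = 0.5,
                                 noise_sigma = 0.001, band = c(562, 598),
                                 seed = 1L) {
  stopifnot(inherits(protocol, "ri_protocol"), inherits(dip, "dip_model"))
  grid <- wavelength_grid(550, 610, step_nm)
  times <- seq(period_s / 2, protocol$total_s, by = period_s)
  ns <- evaluate_protocol(protocol, times)
  spectra <- matrix(NA_real_, length(grid$values), length(times))
  lam_raw <- numeric(length(times))
  withr::with_seed(as.integer(seed), {
    for (k in seq_along(times)) {
      clean <- spr_spectrum(dip, ns[k], grid)
      noisy <- clean$values + stats::rnorm(length(clean$values), sd = noise_sigma)
      spectra[, k] <- noisy
      lam_raw[k] <- suppressWarnings(
        as.numeric(find_dip(new_spectrum(grid, noisy), band = band)))
    }
  })
  out <- data.frame(time = times, n = ns, lambda_raw = lam_raw)
  attr(out, "spectra") <- spectra
  attr(out, "grid") <- grid
  out
}

#' Spectral-shift calibration over staircase states
#'
#' For each constant-index state: the spectra acquired in the state are
#' averaged and a Gaussian dip is fitted to the mean spectrum (the
#' state-level dip wavelength), while the scatter of the raw per-spectrum
#' minima gives the state's wavelength noise. Sensitivity is the OLS slope
#' of state dip wavelength versus index; baseline noise is, by the
#' reference convention, the worst (maximum) state noise, and
#' `LOD = noise / |slope|`.
#'
#' @param readout Output of [simulate_dip_readout()] (or a compatible data
#'   frame with attributes `spectra` and `grid`).
#' @param states Data frame with `n`, `t_start`, `t_end` (see
#'   [protocol_states()]).
#' @param band Dip search band.
#' @param noise_stat `"max"` (default), `"mean"` or `"pooled"` combination
#'   of the per-state noise values.
#' @return A [calibration_result()] in spectral-shift mode, with the
#'   per-state table attached as attribute `"states"`.
#' @export
calibrate_dip <- function(readout, states, band = c(562, 598),
                          noise_stat = c("max", "mean", "pooled")) {
  noise_stat <- match.arg(noise_stat)
  spectra <- attr(readout, "spectra")
  grid <- attr(readout, "grid")
  if (is.null(spectra) || is.null(grid))
    stop("`readout` must carry spectra and grid attributes")
  st <- states
  st$lambda_fit <- NA_real_
  st$lambda_sd <- NA_real_
  for (k in seq_len(nrow(st))) {
    sel <- readout$time >= st$t_start[k] & readout$time <= st$t_end[k]
    if (sum(sel) < 2L) stop("fewer than two spectra in a state window")
    mean_spec <- new_spectrum(grid, rowMeans(spectra[, sel, drop = FALSE]))
    # fit over the full measured span: windowing to the passband truncates
    # the red flank once the dip nears the cut-off and destabilises lambda0
    fitted <- fit_gaussian_dip(mean_spec)
    st$lambda_fit[k] <- fitted$lambda0
    st$lambda_sd[k] <- stats::sd(readout$lambda_raw[sel])
  }
  fit <- fit_sensitivity(st$n, st$lambda_fit)
  noise <- switch(noise_stat,
                  max = max(st$lambda_sd),
                  mean = mean(st$lambda_sd),
                  pooled = sqrt(mean(st$lambda_sd^2)))
  out <- calibration_result("spectral_shift", sensitivity = fit$slope,
                            intercept = fit$intercept,
                            r_squared = fit$r_squared,
                            baseline_noise = noise, response_unit = "nm")
  attr(out, "states") <- st
  out
}

#' Gamma-mode calibration over staircase states
#'
#' Per state: mean and standard deviation of the frame-level ROI gamma
#' means. Sensitivity is the OLS slope of state mean gamma versus index;
#' baseline noise is the worst state standard deviation by default.
#'
#' @param series A `gamma_series` from [roi_timeseries()].
#' @param states Data frame with `n`, `t_start`, `t_end`.
#' @param noise_stat As in [calibrate_dip()].
#' @return A [calibration_result()] in gamma mode, with the per-state
#'   table attached as attribute `"states"`.
#' @export
calibrate_gamma <- function(series, states,
                            noise_stat = c("max", "mean", "pooled")) {
  noise_stat <- match.arg(noise_stat)
  stopifnot(inherits(series, "gamma_series"))
  st <- states
  st$gamma_mean <- NA_real_
  st$gamma_sd <- NA_real_
  for (k in seq_len(nrow(st))) {
    sel <- series$time_s >= st$t_start[k] & series$time_s <= st$t_end[k] &
      is.finite(series$gamma_mean)
    if (sum(sel) < 2L) stop("fewer than two frames in a state window")
    st$gamma_mean[k] <- mean(series$gamma_mean[sel])
    st$gamma_sd[k] <- stats::sd(series$gamma_mean[sel])
  }
  fit <- fit_sensitivity(st$n, st$gamma_mean)
  noise <- switch(noise_stat,
                  max = max(st$gamma_sd),
                  mean = mean(st$gamma_sd),
                  pooled = sqrt(mean(st$gamma_sd^2)))
  out <- calibration_result("gamma", sensitivity = fit$slope,
                            intercept = fit$intercept,
                            r_squared = fit$r_squared,
                            baseline_noise = noise, response_unit = "a.u.")
  attr(out, "states") <- st
  out
}
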