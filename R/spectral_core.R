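# Wavelength-domain forward model: band-pass filters, the Gaussian SPR dip,
# band-intensity integration, the gamma contrast statistic, and dip tracking.

# Fraction of the full raised-cosine edge length that lies between the 50 %
# and 0.005 % (of peak) transmission points. Used to convert the quoted
# edge steepness (a 50 % -> 0.005 % span) into the cosine half-period.
.edge_u_span <- (2 / pi) * acos(sqrt(5e-5)) - 0.5

#' Smooth-edged band-pass filter transmittance
#'
#' Builds a rectangular passband with raised-cosine edges. Edge steepness is
#' parameterised the way interference-filter data sheets quote it: as the
#' wavelength span between the 50 % and 0.005 % (of peak) transmission
#' points. The cut-on and cut-off wavelengths are the 50 % points, so the
#' transmittance at `cut_on` and `cut_off` is exactly `peak / 2`, and the
#' interior plateau transmits `peak`.
#'
#' @param cut_on,cut_off 50 % transmission wavelengths in nm (`cut_on <
#'   cut_off`). Both must lie within the grid span.
#' @param peak Plateau transmittance, in (0, 1].
#' @param edge_width 50 % to 0.005 % span of each edge, nm.
#' @param grid A [wavelength_grid()].
#' @return A `spectrum` carrying a `"passband"` attribute with the design
#'   parameters.
#' @examples
#' g <- wavelength_grid()
#' fA <- make_passband(583, 598, peak = 0.85, edge_width = 4.5, grid = g)
#' @export
make_passband <- function(cut_on, cut_off, peak = 0.85, edge_width = 4.5, grid) {
  stopifnot(is.numeric(cut_on), is.numeric(cut_off))
  if (cut_on >= cut_off) stop("`cut_on` must be below `cut_off`")
  if (peak <= 0 || peak > 1) stop("`peak` must lie in (0, 1]")
  if (edge_width <= 0) stop("`edge_width` must be positive")
  if (cut_on < grid$lambda_min || cut_off > grid$lambda_max)
    stop("passband lies outside the wavelength grid")
  L <- edge_width / .edge_u_span  # full edge length (plateau -> zero)
  if (cut_off - cut_on <= L)
    stop("passband too narrow: edges overlap and no plateau exists")
  lam <- grid$values
  # u runs 0 on the plateau to 1 where transmission reaches zero
  u_rise <- (cut_on + L / 2 - lam) / L
  u_fall <- (lam - (cut_off - L / 2)) / L
  u <- pmin(pmax(pmax(u_rise, u_fall), 0), 1)
  t <- peak * cos(pi * u / 2)^2
  out <- new_spectrum(grid, t)
  attr(out, "passband") <- list(cut_on = cut_on, cut_off = cut_off,
                                peak = peak, edge_width = edge_width)
  out
}

#' Gaussian SPR resonance dip with linear refractive-index response
#'
#' Phenomenological model of the sensor resonance as seen through the
#' collection optics: a Gaussian dip of standard deviation `width_nm` and
#' fractional `depth` sitting on a flat `baseline`, whose centre red-shifts
#' linearly with the bulk refractive index at `sensitivity_nm_riu`
#' (default 244.7 nm/RIU, the measured bulk sensitivity of the gold
#' grating chip).
#'
#' @param lambda0 Dip centre at the reference index `n0`, nm.
#' @param n0 Reference refractive index (RIU).
#' @param sensitivity_nm_riu Linear dip shift, nm per RIU. May be `NA` for
#'   a dip fitted at a single, fixed index.
#' @param width_nm Gaussian standard deviation, nm.
#' @param depth,baseline Fractional dip depth and off-resonance reflectance;
#'   `0 <= depth <= baseline <= 1`.
#' @return An object of class `dip_model`.
#' @export
dip_model <- function(lambda0 = 593, n0 = 1.333, sensitivity_nm_riu = 244.7,
                      width_nm = 8, depth = 0.5, baseline = 0.9) {
  if (width_nm <= 0) stop("`width_nm` must be positive")
  if (depth < 0 || depth > baseline || baseline > 1)
    stop("need 0 <= depth <= baseline <= 1")
  structure(
    list(lambda0 = lambda0, n0 = n0, sensitivity_nm_riu = sensitivity_nm_riu,
         width_nm = width_nm, depth = depth, baseline = baseline),
    class = "dip_model"
  )
}

#' @export
print.dip_model <- function(x, ...) {
  cat(sprintf(
    "<dip_model> centre %.2f nm at n = %.4f, slope %s nm/RIU, sigma %.2f nm, depth %.2f on baseline %.2f\n",
    x$lambda0, x$n0,
    if (is.na(x$sensitivity_nm_riu)) "NA" else sprintf("%.1f", x$sensitivity_nm_riu),
    x$width_nm, x$depth, x$baseline))
  invisible(x)
}

#' Dip centre wavelength at a given refractive index
#'
#' @param dip A [dip_model()].
#' @param n Refractive index (RIU), vectorised.
#' @return Dip centre wavelength(s) in nm.
#' @export
dip_center <- function(dip, n) {
  stopifnot(inherits(dip, "dip_model"))
  dip$lambda0 + dip$sensitivity_nm_riu * (n - dip$n0)
}

#' SPR reflectance spectrum at a given refractive index
#'
#' Evaluates `R(lambda) = baseline - depth * exp(-(lambda - lambda_dip(n))^2
#' / (2 width^2))` on the grid.
#'
#' @inheritParams dip_center
#' @param grid A [wavelength_grid()].
#' @param n_range Sanity bounds for `n`; refractive indices of aqueous
#'   running buffers fall well inside the default.
#' @return A `spectrum`.
#' @export
spr_spectrum <- function(dip, n, grid, n_range = c(1.30, 1.40)) {
  stopifnot(inherits(dip, "dip_model"), length(n) == 1L)
  if (n < n_range[1L] || n > n_range[2L])
    stop(sprintf("n = %.4f outside the allowed range [%.3f, %.3f]", n,
                 n_range[1L], n_range[2L]))
  ctr <- dip_center(dip, n)
  r <- dip$baseline - dip$depth * exp(-(grid$values - ctr)^2 / (2 * dip$width_nm^2))
  new_spectrum(grid, r)
}

#' Band intensity: filtered, illuminated reflectance integrated over wavelength
#'
#' Trapezoidal integral of the pointwise product reflectance x filter x
#' illumination over the shared grid. Units are relative intensity times nm.
#'
#' @param reflectance,filter A `spectrum` each, on the same grid.
#' @param illumination Optional illumination `spectrum`; `NULL` means a flat
#'   (unit) source.
#' @return A single non-negative number.
#' @export
band_intensity <- function(reflectance, filter, illumination = NULL) {
  stopifnot(inherits(reflectance, "spectrum"), inherits(filter, "spectrum"))
  if (is.null(illumination)) {
    assert_same_grid(reflectance, filter)
    prod <- reflectance$values * filter$values
  } else {
    assert_same_grid(reflectance, filter, illumination)
    prod <- reflectance$values * filter$values * illumination$values
  }
  pracma::trapz(reflectance$grid$values, prod)
}

#' Spectral contrast response gamma
#'
#' The ratiometric statistic read out by the dual-band filter array:
#' `gamma = (I_A - I_B) / (I_A + I_B) = (2 I_A - I_AB) / I_AB`, where `I_A`
#' is the intensity through the narrow filter (band 1), `I_B = I_AB - I_A`
#' the remainder of the wide passband (band 2), and `I_AB` the combined
#' intensity. Bounded in [-1, 1] for physical band intensities
#' (`0 <= I_A <= I_AB`); its sign tracks red/blue shifts of the resonance.
#'
#' @param I_A,I_AB Band intensities (vectorised; recycled to a common
#'   length). `I_AB` must be strictly positive.
#' @return gamma, dimensionless (a.u.).
#' @examples
#' gamma_value(0.5, 1)   # balanced bands -> 0
#' gamma_value(0.6, 1)   # red-weighted  -> 0.2
#' @export
gamma_value <- function(I_A, I_AB) {
  if (any(!is.finite(I_A)) || any(!is.finite(I_AB)))
    stop("band intensities must be finite")
  if (any(I_A < 0)) stop("`I_A` must be non-negative")
  if (any(I_AB <= 0)) stop("`I_AB` must be strictly positive")
  (2 * I_A - I_AB) / I_AB
}

# band argument normaliser: a passband spectrum or c(cut_on, cut_off)
band_limits <- function(band) {
  if (inherits(band, "spectrum")) {
    pb <- attr(band, "passband")
    if (is.null(pb)) stop("spectrum has no passband metadata; pass c(cut_on, cut_off)")
    c(pb$cut_on, pb$cut_off)
  } else {
    stopifnot(is.numeric(band), length(band) == 2L, band[1L] < band[2L])
    band
  }
}

#' Locate the resonance dip as the in-band intensity minimum
#'
#' Finds the wavelength of the minimum sample within the search band (the
#' wide-filter bandwidth, in the reference experiment). With `refine =
#' TRUE`, a three-point quadratic interpolation around the argmin gives a
#' sub-sample estimate; the raw minimum is the default, matching how the
#' reference dips were read off a spectrometer.
#'
#' @param spectrum A `spectrum`.
#' @param band Search band: a passband `spectrum` (its 50 % limits are used)
#'   or `c(cut_on, cut_off)` in nm. Default is the wide-filter band.
#' @param refine Logical; apply quadratic refinement around the minimum.
#' @return Dip wavelength in nm, with a logical attribute `on_boundary`
#'   (`TRUE`, with a warning, when the minimum sits on the band edge and
#'   the dip may have left the window).
#' @export
find_dip <- function(spectrum, band = c(562, 598), refine = FALSE) {
  stopifnot(inherits(spectrum, "spectrum"))
  bl <- band_limits(band)
  lam <- spectrum$grid$values
  sel <- which(lam >= bl[1L] & lam <= bl[2L])
  if (length(sel) < 3L) stop("search band overlaps fewer than three grid samples")
  y <- spectrum$values[sel]
  if (max(y) - min(y) < 1e-12) stop("spectrum is constant within the search band")
  k <- which.min(y)
  on_boundary <- k == 1L || k == length(sel)
  if (on_boundary)
    warning("intensity minimum lies on the search-band boundary; the dip may have left the window")
  lam_min <- lam[sel[k]]
  if (refine && !on_boundary) {
    h <- spectrum$grid$step
    yl <- y[k - 1L]; y0 <- y[k]; yr <- y[k + 1L]
    denom <- yl - 2 * y0 + yr
    if (denom > 0) lam_min <- lam_min + h * (yl - yr) / (2 * denom)
  }
  structure(lam_min, on_boundary = on_boundary)
}

#' Fit a Gaussian dip to a measured spectrum
#'
#' Least-squares fit of `baseline - depth * exp(-(lambda - lambda0)^2 /
#' (2 width^2))`, the model used to convert a measured resonance curve into
#' a smooth dip for the theoretical-sensitivity calculation. Initial values
#' are derived from the data unless supplied.
#'
#' @param spectrum A `spectrum` exhibiting an interior minimum.
#' @param window Optional `c(min, max)` nm restricting the fit.
#' @param init Optional [dip_model()] providing starting values.
#' @return A [dip_model()] at fixed index (`sensitivity_nm_riu = NA`,
#'   `n0 = NA`), with attributes `residual_norm` (L2 norm of residuals) and
#'   `fit` (the underlying `nls` object).
#' @export
fit_gaussian_dip <- function(spectrum, window = NULL, init = NULL) {
  stopifnot(inherits(spectrum, "spectrum"))
  lam <- spectrum$grid$values
  y <- spectrum$values
  if (!is.null(window)) {
    sel <- which(lam >= window[1L] & lam <= window[2L])
    lam <- lam[sel]; y <- y[sel]
  }
  if (length(lam) < 5L) stop("too few samples in the fit window")
  if (max(y) - min(y) < 1e-10) stop("flat spectrum: no dip to fit")
  k <- which.min(y)
  if (k <= 1L || k >= length(y))
    stop("no interior minimum in the fit window (monotonic input?)")
  if (is.null(init)) {
    depth0 <- max(y) - min(y)
    # half-width at half-depth as a sigma guess
    below <- y <= min(y) + depth0 / 2
    hw <- (sum(below) * mean(diff(lam))) / 2
    init <- list(lambda0 = lam[k], width_nm = max(hw / sqrt(2 * log(2)), mean(diff(lam))),
                 depth = depth0, baseline = max(y))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ baseline - depth * exp(-(lam - lambda0)^2 / (2 * width^2)),
      start = list(lambda0 = init$lambda0, width = init$width_nm,
                   depth = init$depth, baseline = init$baseline),
      lower = c(lambda0 = min(lam), width = 1e-3, depth = 0, baseline = 0),
      upper = c(lambda0 = max(lam), width = Inf, depth = Inf, baseline = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian dip fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  out <- dip_model(lambda0 = unname(cf["lambda0"]), n0 = NA_real_,
                   sensitivity_nm_riu = NA_real_,
                   width_nm = unname(cf["width"]),
                   depth = min(unname(cf["depth"]), unname(cf["baseline"])),
                   baseline = min(unname(cf["baseline"]), 1))
  attr(out, "residual_norm") <- sqrt(sum(stats::resid(fit)^2))
  attr(out, "fit") <- fit
  out
}
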