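# Transfer-matrix optics for stratified dielectric stacks (the SiO2/Ta2O5
# interference filters of the array). Standard 2x2 characteristic-matrix
# formalism; admittances in units of the free-space admittance.

#' Homogeneous thin-film layer
#'
#' @param index Complex refractive index (Im >= 0 for lossy media).
#' @param thickness_nm Physical thickness in nm (>= 0).
#' @return An object of class `tmm_layer`.
#' @export
tmm_layer <- function(index, thickness_nm) {
  index <- as.complex(index)
  if (Im(index) < 0) stop("Im(index) must be >= 0 (passive medium)")
  if (thickness_nm < 0) stop("`thickness_nm` must be >= 0")
  structure(list(index = index, thickness_nm = thickness_nm), class = "tmm_layer")
}

#' Multilayer stack between two semi-infinite media
#'
#' Layers are ordered from the incident side. An empty layer list is a bare
#' interface between the two media.
#'
#' @param layers List of [tmm_layer()] objects (possibly empty).
#' @param n_incident,n_substrate Real indices of the entry and exit media.
#' @return An object of class `tmm_stack`.
#' @export
tmm_stack <- function(layers = list(), n_incident = 1, n_substrate = 1.5) {
  stopifnot(is.list(layers))
  for (l in layers) if (!inherits(l, "tmm_layer")) stop("`layers` must contain tmm_layer objects")
  if (!is.numeric(n_incident) || n_incident < 1 || !is.numeric(n_substrate) || n_substrate < 1)
    stop("media indices must be real numbers >= 1")
  structure(list(layers = layers, n_incident = n_incident, n_substrate = n_substrate),
            class = "tmm_stack")
}

#' @export
print.tmm_stack <- function(x, ...) {
  cat(sprintf("<tmm_stack> %d layer(s), %.3g -> %.3g\n",
              length(x$layers), x$n_incident, x$n_substrate))
  invisible(x)
}

# cosine of the propagation angle in a medium of index n, given the
# conserved transverse component kx = n_in * sin(theta_in)
.cos_theta <- function(n, kx) sqrt(1 + 0i - (kx / n)^2)

# tilted optical admittance (free-space units)
.admittance <- function(n, cos_t, polarization) {
  switch(polarization, TE = n * cos_t, TM = n / cos_t,
         stop("`polarization` must be \"TE\" or \"TM\""))
}

#' Characteristic matrix of one layer
#'
#' The unimodular 2x2 matrix relating tangential fields across a layer,
#' with phase thickness `delta = 2 pi n d cos(theta) / lambda` and the
#' polarization-dependent tilted admittance.
#'
#' @param layer A [tmm_layer()].
#' @param wavelength Vacuum wavelength, nm.
#' @param angle Incidence angle in the entry medium, radians.
#' @param polarization `"TE"` or `"TM"`.
#' @param n_incident Entry-medium index (sets the conserved transverse
#'   wavevector for oblique incidence).
#' @return A 2x2 complex matrix.
#' @export
characteristic_matrix <- function(layer, wavelength, angle = 0,
                                  polarization = c("TE", "TM"), n_incident = 1) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(layer, "tmm_layer"))
  if (wavelength <= 0) stop("`wavelength` must be positive")
  if (abs(angle) >= pi / 2) stop("grazing/evanescent incidence is not supported")
  kx <- n_incident * sin(angle)
  ct <- .cos_theta(layer$index, kx)
  eta <- .admittance(layer$index, ct, polarization)
  delta <- 2 * pi * layer$index * layer$thickness_nm * ct / wavelength
  matrix(c(cos(delta), 1i * eta * sin(delta),
           1i * sin(delta) / eta, cos(delta)), 2L, 2L)
}

# reflection/transmission of a full stack at one wavelength
stack_rt <- function(stack, wavelength, angle = 0, polarization = "TE") {
  kx <- stack$n_incident * sin(angle)
  M <- diag(2) + 0i
  for (l in stack$layers)
    M <- M %*% characteristic_matrix(l, wavelength, angle, polarization,
                                     n_incident = stack$n_incident)
  eta_in <- .admittance(stack$n_incident + 0i, .cos_theta(stack$n_incident, kx),
                        polarization)
  eta_out <- .admittance(stack$n_substrate + 0i, .cos_theta(stack$n_substrate, kx),
                         polarization)
  bc <- M %*% c(1, eta_out)
  B <- bc[1L]; C <- bc[2L]
  r <- (eta_in * B - C) / (eta_in * B + C)
  list(r = r,
       R = Mod(r)^2,
       T = 4 * Re(eta_in) * Re(eta_out) / Mod(eta_in * B + C)^2)
}

#' Stack transmittance spectrum
#'
#' @param stack A [tmm_stack()].
#' @param grid A [wavelength_grid()].
#' @param angle Incidence angle, radians.
#' @param polarization `"TE"` or `"TM"`.
#' @return A `spectrum` of intensity transmittance. For lossless stacks
#'   `T + R = 1` to numerical precision.
#' @export
stack_transmittance <- function(stack, grid, angle = 0, polarization = c("TE", "TM")) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "tmm_stack"), inherits(grid, "wavelength_grid"))
  t <- vapply(grid$values,
              function(wl) stack_rt(stack, wl, angle, polarization)$T, numeric(1L))
  new_spectrum(grid, t)
}

#' @rdname stack_transmittance
#' @return `stack_reflectance()` returns the reflectance spectrum.
#' @export
stack_reflectance <- function(stack, grid, angle = 0, polarization = c("TE", "TM")) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "tmm_stack"), inherits(grid, "wavelength_grid"))
  r <- vapply(grid$values,
              function(wl) stack_rt(stack, wl, angle, polarization)$R, numeric(1L))
  new_spectrum(grid, r)
}

#' Quarter-wave Bragg mirror builder
#'
#' Alternating high/low-index quarter-wave layers at the design wavelength.
#' Default indices are non-dispersive Ta2O5 (2.10) and SiO2 (1.46).
#'
#' @param pairs Number of high/low pairs.
#' @param lambda_design Design wavelength, nm.
#' @param n_high,n_low Layer indices.
#' @param n_incident,n_substrate Bounding media.
#' @param first Which index starts on the incident side.
#' @return A [tmm_stack()].
#' @export
dbr_stack <- function(pairs, lambda_design, n_high = 2.10, n_low = 1.46,
                      n_incident = 1, n_substrate = 1.5,
                      first = c("high", "low")) {
  first <- match.arg(first)
  if (pairs < 1L) stop("`pairs` must be >= 1")
  dH <- lambda_design / (4 * n_high)
  dL <- lambda_design / (4 * n_low)
  one_pair <- if (first == "high")
    list(tmm_layer(n_high, dH), tmm_layer(n_low, dL))
  else
    list(tmm_layer(n_low, dL), tmm_layer(n_high, dH))
  tmm_stack(rep(one_pair, pairs), n_incident, n_substrate)
}

#' Quarter-wave cavity band-pass builder
#'
#' A Fabry-Perot band-pass: two quarter-wave Bragg mirrors enclosing a
#' half-wave spacer, giving a narrow transmission peak at the design
#' wavelength. This is the generic stand-in for the array's interference
#' filters when exploring stack behaviour such as etch-stop insensitivity.
#'
#' @param mirror_pairs Quarter-wave pairs in each mirror.
#' @param lambda_design Design wavelength, nm.
#' @param n_high,n_low Layer indices (defaults Ta2O5 / SiO2).
#' @param n_spacer Spacer index (default the low-index material).
#' @param n_incident,n_substrate Bounding media.
#' @return A [tmm_stack()].
#' @export
bandpass_stack <- function(mirror_pairs, lambda_design, n_high = 2.10,
                           n_low = 1.46, n_spacer = n_low,
                           n_incident = 1, n_substrate = 1.5) {
  m1 <- dbr_stack(mirror_pairs, lambda_design, n_high, n_low, first = "high")$layers
  spacer <- list(tmm_layer(n_spacer, lambda_design / (2 * n_spacer)))
  m2 <- rev(dbr_stack(mirror_pairs, lambda_design, n_high, n_low, first = "high")$layers)
  tmm_stack(c(m1, spacer, m2), n_incident, n_substrate)
}

# transmittance-weighted spectral centroid within a band (robust to ripple)
.band_centroid <- function(spectrum, band) {
  bl <- band_limits(band)
  lam <- spectrum$grid$values
  sel <- lam >= bl[1L] & lam <= bl[2L]
  t <- spectrum$values[sel]
  if (max(t) - min(t) < 1e-3)
    stop("no spectral feature within the band (near-constant transmittance)")
  sum(lam[sel] * t) / sum(t)
}

#' Spectral shift induced by an incident-side overlayer
#'
#' Prepends a dielectric overlayer (the etch-stop material, by default
#' SiO2) of each requested thickness to the stack and reports the shift of
#' the transmittance-weighted spectral centroid within the band, relative
#' to zero overlayer. Reproduces the design property that an etch-stop
#' layer up to ~220 nm barely moves the underlying filter's response.
#'
#' @param stack A [tmm_stack()].
#' @param thicknesses_nm Overlayer thicknesses to scan, nm.
#' @param band Band within which the feature centroid is computed
#'   (`c(min, max)` nm or a passband spectrum).
#' @param grid A [wavelength_grid()].
#' @param overlayer_index Overlayer refractive index (default SiO2, 1.46).
#' @param angle,polarization Propagation geometry.
#' @return A data frame with columns `thickness_nm` and `shift_nm`.
#' @export
overlayer_shift_scan <- function(stack, thicknesses_nm, band, grid,
                                 overlayer_index = 1.46, angle = 0,
                                 polarization = "TE") {
  stopifnot(inherits(stack, "tmm_stack"))
  base <- .band_centroid(stack_transmittance(stack, grid, angle, polarization), band)
  shifts <- vapply(thicknesses_nm, function(d) {
    if (d == 0) return(0)
    with_ol <- tmm_stack(c(list(tmm_layer(overlayer_index, d)), stack$layers),
                         stack$n_incident, stack$n_substrate)
    .band_centroid(stack_transmittance(with_ol, grid, angle, polarization), band) - base
  }, numeric(1L))
  data.frame(thickness_nm = thicknesses_nm, shift_nm = shifts)
}
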