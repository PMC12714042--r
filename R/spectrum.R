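#' Uniform wavelength grid
#'
#' All spectra in the package (filter transmittances, illumination, SPR
#' reflectance) live on a shared, uniformly spaced wavelength axis in
#' nanometres. The default covers 555--605 nm at 0.1 nm, which spans both
#' filter passbands (562--598 nm) with room for the resonance dip to shift.
#'
#' @param lambda_min,lambda_max Grid limits in nm.
#' @param step Sample spacing in nm; must be positive.
#' @return An object of class `wavelength_grid` with fields `lambda_min`,
#'   `lambda_max`, `step` and the sample vector `values`.
#' @examples
#' g <- wavelength_grid(555, 605, 0.1)
#' length(g$values)
#' @export
wavelength_grid <- function(lambda_min = 555, lambda_max = 605, step = 0.1) {
  stopifnot(is.numeric(lambda_min), is.numeric(lambda_max), is.numeric(step))
  if (step <= 0) stop("`step` must be positive")
  if (lambda_max <= lambda_min) stop("`lambda_max` must exceed `lambda_min`")
  values <- seq(lambda_min, lambda_max, by = step)
  if (length(values) < 2L) stop("grid must contain at least two samples")
  structure(
    list(lambda_min = lambda_min, lambda_max = values[length(values)],
         step = step, values = values),
    class = "wavelength_grid"
  )
}

#' @export
length.wavelength_grid <- function(x) length(x$values)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %.4g--%.4g nm, step %.4g nm (%d samples)\n",
              x$lambda_min, x$lambda_max, x$step, length(x$values)))
  invisible(x)
}

#' Sampled spectrum on a wavelength grid
#'
#' A spectrum is a sampled function of wavelength: a filter transmittance,
#' an illumination profile, or an SPR reflectance. Transmittance-like
#' spectra are expected to stay within [0, 1]; relative intensities are
#' merely non-negative.
#'
#' @param grid A [wavelength_grid()].
#' @param values Numeric vector, one sample per grid point.
#' @return An object of class `spectrum` (list with `grid` and `values`).
#' @export
new_spectrum <- function(grid, values) {
  stopifnot(inherits(grid, "wavelength_grid"), is.numeric(values))
  if (length(values) != length(grid$values))
    stop("`values` must have one sample per grid point")
  if (anyNA(values)) stop("spectrum values must not contain NA")
  structure(list(grid = grid, values = as.numeric(values)), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d samples on %.4g--%.4g nm, range [%.4g, %.4g]\n",
              length(x$values), x$grid$lambda_min, x$grid$lambda_max,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$grid$values, value = x$values)
}

# error unless two spectra share one wavelength axis
assert_same_grid <- function(...) {
  specs <- list(...)
  ref <- specs[[1L]]$grid$values
  for (s in specs[-1L]) {
    g <- s$grid$values
    if (length(g) != length(ref) || max(abs(g - ref)) > 1e-9)
      stop("spectra are defined on different wavelength grids")
  }
  invisible(TRUE)
}

#' Read / write spectra as two-column CSV
#'
#' The on-disk exchange format for all spectra is a two-column CSV with a
#' header `wavelength_nm,value`. On read, a uniform grid is reconstructed
#' from the wavelength column; optionally the samples are interpolated onto
#' a caller-supplied grid.
#'
#' @param path File path.
#' @param grid Optional target [wavelength_grid()]; if given, samples are
#'   linearly interpolated onto it (no extrapolation: the file must cover
#'   the grid).
#' @return A `spectrum`.
#' @export
read_spectrum_csv <- function(path, grid = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop("spectrum CSV must have columns `wavelength_nm` and `value`")
  wl <- df$wavelength_nm
  if (is.unsorted(wl, strictly = TRUE)) stop("wavelengths must be strictly increasing")
  if (!is.null(grid)) {
    if (grid$lambda_min < wl[1L] || grid$lambda_max > wl[length(wl)])
      stop("file does not cover the requested grid")
    v <- stats::approx(wl, df$value, xout = grid$values)$y
    return(new_spectrum(grid, v))
  }
  steps <- diff(wl)
  if (max(steps) - min(steps) > 1e-6)
    stop("file wavelengths are not uniformly spaced; pass `grid` to interpolate")
  g <- wavelength_grid(wl[1L], wl[length(wl)], mean(steps))
  new_spectrum(g, df$value[seq_along(g$values)])
}

#' @rdname read_spectrum_csv
#' @param spectrum A `spectrum` to write.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum"))
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}
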