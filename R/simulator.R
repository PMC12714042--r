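# Synthetic dual-band spectral image (DBSI) generator: checkerboard mosaic
# geometry, refractive-index protocols, the forward optical model per tile
# class, grid-boundary artifacts, and detector noise.

#' Checkerboard mosaic geometry
#'
#' Describes the filter-unit layout on the sensor: square tiles of
#' `tile_px` pixels (one 10 x 10 um filter unit each), in a checkerboard of
#' two filter classes. Tile `(i, j)` (0-based row/column) carries the
#' narrow A filter iff `(i + j + parity)` is even.
#'
#' @param n_tiles_x,n_tiles_y Tile counts along image columns and rows.
#' @param tile_px Pixels per tile side (integer >= 1).
#' @param parity Checkerboard phase of the A filter, 0 or 1.
#' @return An object of class `mosaic_geometry`.
#' @export
mosaic_geometry <- function(n_tiles_x, n_tiles_y, tile_px = 4, parity = 0) {
  if (n_tiles_x < 1 || n_tiles_y < 1) stop("tile counts must be positive")
  if (tile_px < 1) stop("`tile_px` must be >= 1")
  if (!parity %in% c(0, 1)) stop("`parity` must be 0 or 1")
  structure(
    list(n_tiles_x = as.integer(n_tiles_x), n_tiles_y = as.integer(n_tiles_y),
         tile_px = as.integer(tile_px), parity = as.integer(parity)),
    class = "mosaic_geometry"
  )
}

#' @export
print.mosaic_geometry <- function(x, ...) {
  cat(sprintf("<mosaic_geometry> %d x %d tiles of %d px (parity %d), image %d x %d px\n",
              x$n_tiles_y, x$n_tiles_x, x$tile_px, x$parity,
              x$n_tiles_y * x$tile_px, x$n_tiles_x * x$tile_px))
  invisible(x)
}

#' Tile- and pixel-level class maps
#'
#' @param geometry A [mosaic_geometry()].
#' @return `tile_class_map()`: a logical `n_tiles_y x n_tiles_x` matrix,
#'   `TRUE` for A tiles. `pixel_class_map()`: the same expanded to pixels.
#' @export
tile_class_map <- function(geometry) {
  stopifnot(inherits(geometry, "mosaic_geometry"))
  i <- matrix(0:(geometry$n_tiles_y - 1L), geometry$n_tiles_y, geometry$n_tiles_x)
  j <- matrix(0:(geometry$n_tiles_x - 1L), geometry$n_tiles_y, geometry$n_tiles_x,
              byrow = TRUE)
  (i + j + geometry$parity) %% 2L == 0L
}

#' @rdname tile_class_map
#' @export
pixel_class_map <- function(geometry) {
  ones <- matrix(1, geometry$tile_px, geometry$tile_px)
  kronecker(tile_class_map(geometry) * 1L, ones) == 1
}

# pixels within `width` px of any tile boundary (the grid-artifact band)
boundary_pixel_map <- function(geometry, width) {
  np_r <- geometry$n_tiles_y * geometry$tile_px
  np_c <- geometry$n_tiles_x * geometry$tile_px
  off_r <- (seq_len(np_r) - 1L) %% geometry$tile_px
  off_c <- (seq_len(np_c) - 1L) %% geometry$tile_px
  edge_r <- off_r < width | off_r >= geometry$tile_px - width
  edge_c <- off_c < width | off_c >= geometry$tile_px - width
  outer(edge_r, edge_c, `|`)
}

#' Refractive-index protocol segments
#'
#' A protocol is an ordered list of segments played back against time:
#' constant-index steps (buffer/sugar-solution exchanges) and
#' pseudo-first-order Langmuir transients standing in for analyte binding
#' (association toward `delta_n_max` at observed rate `k_obs`) and washing
#' (exponential relaxation toward a residual bound fraction).
#'
#' @param duration_s Segment duration in seconds (> 0).
#' @param n Constant refractive index of a step segment (RIU).
#' @param delta_n_max Saturation index change of an association segment.
#' @param k_obs Observed rate constant, 1/s.
#' @param residual_fraction Fraction of the pre-wash excess index retained
#'   at the end of an infinitely long wash.
#' @return A protocol segment (used by [ri_protocol()]).
#' @export
ri_step <- function(duration_s, n) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  list(kind = "step", duration_s = duration_s, n = n)
}

#' @rdname ri_step
#' @export
ri_langmuir <- function(duration_s, delta_n_max, k_obs) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (k_obs <= 0) stop("`k_obs` must be positive")
  list(kind = "langmuir", duration_s = duration_s,
       delta_n_max = delta_n_max, k_obs = k_obs)
}

#' @rdname ri_step
#' @export
ri_wash <- function(duration_s, k_obs, residual_fraction = 0) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (k_obs <= 0) stop("`k_obs` must be positive")
  if (residual_fraction < 0 || residual_fraction > 1)
    stop("`residual_fraction` must lie in [0, 1]")
  list(kind = "wash", duration_s = duration_s, k_obs = k_obs,
       residual_fraction = residual_fraction)
}

#' Assemble a refractive-index protocol
#'
#' The first segment must be a step (it sets the starting level); later
#' Langmuir/wash segments evolve continuously from the level reached at
#' the previous segment's end. Washes relax toward the last step level
#' plus `residual_fraction` of the excess accumulated since then.
#'
#' @param ... Segments from [ri_step()], [ri_langmuir()], [ri_wash()].
#' @param n_bounds Allowed index range; the protocol must stay inside it.
#' @return An object of class `ri_protocol`.
#' @export
ri_protocol <- function(..., n_bounds = c(1.30, 1.40)) {
  segments <- list(...)
  if (length(segments) == 1L && is.null(segments[[1L]]$kind))
    segments <- segments[[1L]]  # allow a pre-built list
  if (length(segments) == 0L) stop("protocol needs at least one segment")
  if (segments[[1L]]$kind != "step") stop("the first segment must be a step")
  starts <- cumsum(c(0, vapply(segments, `[[`, numeric(1L), "duration_s")))
  # walk the segments to get each segment's entry level and wash baseline
  level <- NA_real_
  base <- NA_real_
  for (k in seq_along(segments)) {
    s <- segments[[k]]
    segments[[k]]$t_start <- starts[k]
    segments[[k]]$n_enter <- level
    if (s$kind == "step") {
      level <- s$n
      base <- s$n
    } else if (s$kind == "langmuir") {
      segments[[k]]$n_base <- base
      level <- level + s$delta_n_max  # asymptote; exact end level set below
      end_level <- segments[[k]]$n_enter +
        s$delta_n_max * (1 - exp(-s$k_obs * s$duration_s))
      level <- end_level
    } else { # wash
      target <- base + s$residual_fraction * (level - base)
      segments[[k]]$n_target <- target
      level <- target + (level - target) * exp(-s$k_obs * s$duration_s)
    }
    if (level < n_bounds[1L] || level > n_bounds[2L])
      stop(sprintf("protocol leaves the allowed index range [%.3f, %.3f]",
                   n_bounds[1L], n_bounds[2L]))
  }
  structure(list(segments = segments, total_s = starts[length(starts)],
                 n_bounds = n_bounds), class = "ri_protocol")
}

#' Convenience staircase protocol of constant-index states
#'
#' @param levels Refractive indices of the successive states (RIU).
#' @param state_duration_s Dwell time per state, seconds.
#' @return An `ri_protocol` of step segments.
#' @export
ri_staircase <- function(levels = seq(1.333, 1.3495, length.out = 5),
                         state_duration_s = 600) {
  ri_protocol(lapply(levels, function(nn) ri_step(state_duration_s, nn)))
}

#' Evaluate a protocol at sample times
#'
#' @param protocol An [ri_protocol()].
#' @param times Times in seconds, all within `[0, total]`.
#' @return Refractive index (RIU) at each time.
#' @export
evaluate_protocol <- function(protocol, times) {
  stopifnot(inherits(protocol, "ri_protocol"))
  if (any(times < 0 | times > protocol$total_s))
    stop("times outside the protocol span")
  n <- numeric(length(times))
  for (s in protocol$segments) {
    in_seg <- times >= s$t_start & times <= s$t_start + s$duration_s
    if (!any(in_seg)) next
    tp <- times[in_seg] - s$t_start
    n[in_seg] <- switch(
      s$kind,
      step = s$n,
      langmuir = s$n_enter + s$delta_n_max * (1 - exp(-s$k_obs * tp)),
      wash = s$n_target + (s$n_enter - s$n_target) * exp(-s$k_obs * tp))
  }
  n
}

#' State table of a staircase protocol
#'
#' @param protocol An [ri_protocol()] made only of step segments.
#' @return Data frame with columns `n`, `t_start`, `t_end`, one row per
#'   constant-index state.
#' @export
protocol_states <- function(protocol) {
  stopifnot(inherits(protocol, "ri_protocol"))
  segs <- protocol$segments
  if (!all(vapply(segs, `[[`, character(1L), "kind") == "step"))
    stop("state table is only defined for pure step protocols")
  data.frame(
    n = vapply(segs, `[[`, numeric(1L), "n"),
    t_start = vapply(segs, `[[`, numeric(1L), "t_start"),
    t_end = vapply(segs, function(s) s$t_start + s$duration_s, numeric(1L)))
}

#' Detector noise model
#'
#' Gaussian read noise plus optional Poisson shot noise, applied after the
#' noiseless tile intensities are rendered. The seed makes every frame
#' reproducible: rendering twice with the same seed gives bitwise-identical
#' frames.
#'
#' @param read_sigma Read-noise standard deviation, counts (>= 0).
#' @param shot Logical; add Poisson shot noise.
#' @param seed Integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(read_sigma = 2, shot = TRUE, seed = 1L) {
  if (read_sigma < 0) stop("`read_sigma` must be >= 0")
  structure(list(read_sigma = read_sigma, shot = isTRUE(shot),
                 seed = as.integer(seed)), class = "noise_model")
}

# noiseless per-class counts for one refractive-index value
render_band_counts <- function(n, dip, filter_A, filter_AB, illumination, gain) {
  refl <- spr_spectrum(dip, n, filter_A$grid)
  I_A <- band_intensity(refl, filter_A, illumination)
  I_AB <- band_intensity(refl, filter_AB, illumination)
  list(I_A = I_A, I_AB = I_AB,
       counts_A = gain * I_A, counts_AB = gain * I_AB,
       gamma = gamma_value(I_A, I_AB))
}

# default gain: mid-scale ~ `target` counts through the wide filter at the
# dip's reference index
auto_gain <- function(dip, filter_A, filter_AB, illumination = NULL, target = 2000) {
  refl <- spr_spectrum(dip, dip$n0, filter_AB$grid)
  target / band_intensity(refl, filter_AB, illumination)
}

assert_nested_filters <- function(filter_A, filter_AB) {
  assert_same_grid(filter_A, filter_AB)
  if (any(filter_A$values > filter_AB$values + 1e-9))
    stop("filters are not nested: the A passband must lie within AB with T_A <= T_AB")
}

#' Render one synthetic DBSI frame
#'
#' Fills every A tile with `gain * I_A` and every AB tile with
#' `gain * I_AB` from the forward optical model, overwrites a boundary band
#' of `artifact_width` pixels around every tile with a fixed mixture of the
#' two class values (the grid artifact), then applies detector noise and
#' clips to the bit depth. Noiseless output is kept at full floating
#' precision; noisy output is rounded to integer counts.
#'
#' `n` may be a scalar (uniform field) or an `n_tiles_y x n_tiles_x` matrix
#' of per-tile indices, which emulates spatially structured binding.
#'
#' @param geometry A [mosaic_geometry()].
#' @param n Refractive index (RIU): scalar or per-tile matrix.
#' @param dip A [dip_model()].
#' @param filter_A,filter_AB Passband spectra (A nested in AB).
#' @param illumination Optional illumination spectrum (`NULL` = flat).
#' @param gain Counts per band-intensity unit; `NULL` auto-scales so the
#'   wide-band tiles sit near 2000 counts at the dip reference index.
#' @param bit_depth Detector bit depth (clipping ceiling `2^bit_depth - 1`).
#' @param artifact_width Boundary band width in pixels on each tile edge
#'   (0 disables the artifact).
#' @param artifact_mix Mixing fraction of the A-class value in the boundary
#'   band (0.5 = arithmetic mean of the two class values).
#' @param noise A [noise_model()] or `NULL` for noiseless frames.
#' @param timestamp Frame time in seconds (metadata).
#' @return A numeric matrix of detector counts with class `dbsi_frame` and
#'   attributes `geometry`, `timestamp`, `bit_depth` and `truth` (the
#'   noiseless per-class intensities and gamma; for a matrix `n`, the
#'   area-weighted means).
#' @export
render_frame <- function(geometry, n, dip, filter_A, filter_AB,
                         illumination = NULL, gain = NULL, bit_depth = 12,
                         artifact_width = 1, artifact_mix = 0.5,
                         noise = NULL, timestamp = 0) {
  stopifnot(inherits(geometry, "mosaic_geometry"), inherits(dip, "dip_model"))
  assert_nested_filters(filter_A, filter_AB)
  if (artifact_width < 0 || 2 * artifact_width >= geometry$tile_px && artifact_width > 0)
    stop("`artifact_width` must satisfy 0 <= 2*width < tile_px")
  if (is.null(gain)) gain <- auto_gain(dip, filter_A, filter_AB, illumination)

  tiles_A <- tile_class_map(geometry)
  if (is.matrix(n)) {
    if (!all(dim(n) == c(geometry$n_tiles_y, geometry$n_tiles_x)))
      stop("per-tile `n` matrix must be n_tiles_y x n_tiles_x")
    n_tile <- n
  } else {
    n_tile <- matrix(n, geometry$n_tiles_y, geometry$n_tiles_x)
  }
  vals_A <- matrix(NA_real_, nrow(n_tile), ncol(n_tile))
  vals_AB <- vals_A
  uniq <- unique(as.vector(n_tile))
  per_n <- lapply(uniq, render_band_counts, dip = dip, filter_A = filter_A,
                  filter_AB = filter_AB, illumination = illumination, gain = gain)
  for (k in seq_along(uniq)) {
    sel <- n_tile == uniq[k]
    vals_A[sel] <- per_n[[k]]$counts_A
    vals_AB[sel] <- per_n[[k]]$counts_AB
  }
  tile_vals <- ifelse(tiles_A, vals_A, vals_AB)
  ones <- matrix(1, geometry$tile_px, geometry$tile_px)
  img <- kronecker(tile_vals, ones)

  if (artifact_width > 0) {
    art <- kronecker(artifact_mix * vals_A + (1 - artifact_mix) * vals_AB, ones)
    bmap <- boundary_pixel_map(geometry, artifact_width)
    img[bmap] <- art[bmap]
  }

  ceiling_counts <- 2^bit_depth - 1
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    img <- withr::with_seed(noise$seed, {
      out <- img
      if (noise$shot) out <- matrix(stats::rpois(length(out), lambda = pmax(out, 0)),
                                    nrow(out), ncol(out))
      if (noise$read_sigma > 0)
        out <- out + stats::rnorm(length(out), sd = noise$read_sigma)
      out
    })
    img <- round(pmin(pmax(img, 0), ceiling_counts))
  } else {
    img <- pmin(pmax(img, 0), ceiling_counts)
  }

  truth <- list(
    n = n_tile,
    I_A = sum((vals_A / gain) * 1) / length(vals_A),
    I_AB = sum((vals_AB / gain) * 1) / length(vals_AB),
    gamma = gamma_value(mean(vals_A / gain), mean(vals_AB / gain)),
    gain = gain)
  structure(img, class = c("dbsi_frame", class(img)),
            geometry = geometry, timestamp = timestamp,
            bit_depth = bit_depth, truth = truth)
}

#' Render a time sequence of DBSI frames
#'
#' One frame per sample time along a refractive-index protocol, each with
#' an independent (but seed-derived, hence reproducible) noise draw, plus a
#' ground-truth sidecar table for parameter-recovery tests.
#'
#' @inheritParams render_frame
#' @param protocol An [ri_protocol()].
#' @param frame_period_s Seconds between frames (default 20 s: thirty
#'   frames per ten-minute state, as in the reference acquisitions).
#' @return An object of class `frame_stack`: list with `frames` (list of
#'   `dbsi_frame`), `times`, `geometry`, `truth` (data frame: `time`, `n`,
#'   `I_A`, `I_AB`, `gamma`) and the scene parameters.
#' @export
render_sequence <- function(geometry, protocol, dip, filter_A, filter_AB,
                            illumination = NULL, frame_period_s = 20,
                            gain = NULL, bit_depth = 12, artifact_width = 1,
                            artifact_mix = 0.5, noise = noise_model()) {
  stopifnot(inherits(protocol, "ri_protocol"))
  if (protocol$total_s < frame_period_s / 2)
    stop("protocol too short for a single frame")
  times <- seq(frame_period_s / 2, protocol$total_s, by = frame_period_s)
  if (is.null(gain)) gain <- auto_gain(dip, filter_A, filter_AB, illumination)
  ns <- evaluate_protocol(protocol, times)
  frames <- vector("list", length(times))
  truth <- data.frame(time = times, n = ns, I_A = NA_real_, I_AB = NA_real_,
                      gamma = NA_real_)
  for (k in seq_along(times)) {
    nk <- if (is.null(noise)) NULL else
      noise_model(noise$read_sigma, noise$shot, noise$seed + k - 1L)
    fr <- render_frame(geometry, ns[k], dip, filter_A, filter_AB,
                       illumination = illumination, gain = gain,
                       bit_depth = bit_depth, artifact_width = artifact_width,
                       artifact_mix = artifact_mix, noise = nk,
                       timestamp = times[k])
    tr <- attr(fr, "truth")
    truth$I_A[k] <- tr$I_A; truth$I_AB[k] <- tr$I_AB; truth$gamma[k] <- tr$gamma
    frames[[k]] <- fr
  }
  structure(
    list(frames = frames, times = times, geometry = geometry, truth = truth,
         params = list(dip = dip, gain = gain, bit_depth = bit_depth,
                       artifact_width = artifact_width, artifact_mix = artifact_mix,
                       noise = noise, frame_period_s = frame_period_s)),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames of %d x %d px over %.0f s\n",
              length(x$frames), nrow(x$frames[[1L]]), ncol(x$frames[[1L]]),
              max(x$times)))
  invisible(x)
}
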