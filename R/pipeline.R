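# From band images to per-pixel gamma maps, artifact-suppressing Gaussian
# smoothing, ROI time series, and stabilized-state difference images.

#' Per-pixel gamma map from co-registered band images
#'
#' Applies `gamma = (2 I_A - I_AB) / I_AB` elementwise. Pixels whose
#' wide-band intensity falls at or below `intensity_floor` are masked
#' (set to `NA`) rather than propagated, preventing the ratio from blowing
#' up on dark pixels.
#'
#' @param bands A `band_images` object from [demosaic_frame()].
#' @param intensity_floor Counts threshold for masking; defaults to 1 % of
#'   full scale when the bands carry a bit depth, else 0.
#' @return A numeric matrix of class `gamma_frame` with attributes
#'   `n_masked`, `timestamp` and `tile_px`.
#' @export
gamma_map <- function(bands, intensity_floor = NULL) {
  stopifnot(inherits(bands, "band_images"))
  if (!all(dim(bands$I_A) == dim(bands$I_AB)))
    stop("band images have mismatched shapes")
  if (is.null(intensity_floor)) {
    intensity_floor <- if (!is.null(bands$bit_depth))
      0.01 * (2^bands$bit_depth - 1) else 0
  }
  valid <- bands$I_AB > intensity_floor
  g <- matrix(NA_real_, nrow(bands$I_A), ncol(bands$I_A))
  g[valid] <- (2 * bands$I_A[valid] - bands$I_AB[valid]) / bands$I_AB[valid]
  structure(g, class = c("gamma_frame", class(g)),
            n_masked = sum(!valid),
            timestamp = bands$timestamp,
            tile_px = bands$tile_px)
}

# separable Gaussian convolution with circular (wrap) boundary, normalized
# by the valid-pixel weights so masked pixels do not bleed into the result
gauss_smooth_masked <- function(m, sigma) {
  valid <- is.finite(m)
  m0 <- ifelse(valid, m, 0)
  w0 <- valid * 1
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_axis <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    acc <- 0 * x
    for (j in seq_along(k)) {
      o <- j - r - 1L
      idx <- ((seq_len(n) - 1L + o) %% n) + 1L
      acc <- acc + k[j] * (if (along_rows) x[idx, , drop = FALSE]
                           else x[, idx, drop = FALSE])
    }
    acc
  }
  num <- conv_axis(conv_axis(m0, TRUE), FALSE)
  den <- conv_axis(conv_axis(w0, TRUE), FALSE)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  ok <- valid & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Gaussian smoothing of a gamma map
#'
#' Mask-respecting Gaussian convolution used to suppress the tile-boundary
#' grid artifact: the kernel is normalized by the valid-pixel weights, so
#' masked pixels neither receive nor contribute values. Boundaries wrap
#' (the mosaic is periodic), which keeps the spatial mean of a fully valid
#' frame exactly unchanged. `sigma_px = 0` is the identity.
#'
#' @param frame A `gamma_frame`.
#' @param sigma_px Gaussian standard deviation in pixels; defaults to half
#'   a tile, the grid-artifact spatial scale.
#' @return A smoothed `gamma_frame`.
#' @export
smooth_gamma <- function(frame, sigma_px = NULL) {
  stopifnot(inherits(frame, "gamma_frame"))
  if (is.null(sigma_px)) {
    tp <- attr(frame, "tile_px")
    if (is.null(tp)) stop("`sigma_px` must be given when the frame has no tile metadata")
    sigma_px <- tp / 2
  }
  if (sigma_px < 0) stop("`sigma_px` must be >= 0")
  if (sigma_px == 0) return(frame)
  out <- gauss_smooth_masked(unclass_matrix(frame), sigma_px)
  structure(out, class = class(frame),
            n_masked = attr(frame, "n_masked"),
            timestamp = attr(frame, "timestamp"),
            tile_px = attr(frame, "tile_px"))
}

unclass_matrix <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(x))
  m
}

# resolve an ROI spec into a logical mask
resolve_roi <- function(roi, dims, tile_px = NULL) {
  if (is.null(roi)) {
    b <- if (!is.null(tile_px)) tile_px else 0L
    mask <- matrix(FALSE, dims[1L], dims[2L])
    rows <- (b + 1L):(dims[1L] - b); cols <- (b + 1L):(dims[2L] - b)
    if (length(rows) < 1L || length(cols) < 1L)
      stop("frame too small for the default border-trimmed ROI")
    mask[rows, cols] <- TRUE
    return(mask)
  }
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == dims)) stop("ROI mask shape does not match the frames")
    if (!any(roi)) stop("empty ROI")
    return(roi)
  }
  if (is.numeric(roi) && length(roi) == 4L) {  # x0, y0, w, h (1-based, x = column)
    x0 <- roi[1L]; y0 <- roi[2L]; w <- roi[3L]; h <- roi[4L]
    if (w < 1 || h < 1 || x0 < 1 || y0 < 1 ||
        x0 + w - 1 > dims[2L] || y0 + h - 1 > dims[1L])
      stop("ROI rectangle out of bounds")
    mask <- matrix(FALSE, dims[1L], dims[2L])
    mask[y0:(y0 + h - 1), x0:(x0 + w - 1)] <- TRUE
    return(mask)
  }
  stop("`roi` must be NULL, a logical mask, or c(x0, y0, w, h)")
}

#' Interior-pixel mask excluding the grid-artifact band
#'
#' Builds an ROI mask keeping only pixels at least `margin_px` away from
#' every tile boundary (where the grid artifact lives), optionally also
#' trimming whole border tiles.
#'
#' @param dims Frame dimensions `c(rows, cols)`.
#' @param tile_px Pixels per tile side.
#' @param margin_px Pixels to exclude on each side within every tile
#'   (use the simulator's artifact width).
#' @param border_tiles Whole tiles to drop from each image border.
#' @return A logical matrix.
#' @export
interior_pixel_mask <- function(dims, tile_px, margin_px = 1, border_tiles = 0) {
  if (any(dims %% tile_px != 0)) stop("dims must be divisible by `tile_px`")
  if (2 * margin_px >= tile_px) stop("`margin_px` leaves no interior pixels")
  off_r <- (seq_len(dims[1L]) - 1L) %% tile_px
  off_c <- (seq_len(dims[2L]) - 1L) %% tile_px
  in_r <- off_r >= margin_px & off_r < tile_px - margin_px
  in_c <- off_c >= margin_px & off_c < tile_px - margin_px
  mask <- outer(in_r, in_c, `&`)
  if (border_tiles > 0) {
    bt <- border_tiles * tile_px
    mask[c(seq_len(bt), (dims[1L] - bt + 1L):dims[1L]), ] <- FALSE
    mask[, c(seq_len(bt), (dims[2L] - bt + 1L):dims[2L])] <- FALSE
  }
  if (!any(mask)) stop("interior mask is empty")
  mask
}

#' ROI time series of mean gamma
#'
#' @param frames A list of `gamma_frame` objects (e.g. one per time point).
#' @param roi `NULL` (full frame minus a one-tile border), a logical mask,
#'   or a rectangle `c(x0, y0, w, h)` (1-based, x = column).
#' @param times Optional frame times in seconds; taken from frame
#'   timestamps when omitted.
#' @return A data frame of class `gamma_series` with columns `time_s`,
#'   `gamma_mean`, `gamma_sd`, `n_valid`. Frames with no valid ROI pixel
#'   yield `NA` means (a flagged gap) with a warning.
#' @export
roi_timeseries <- function(frames, roi = NULL, times = NULL) {
  stopifnot(is.list(frames), length(frames) > 0L)
  dims <- dim(frames[[1L]])
  mask <- resolve_roi(roi, dims, tile_px = attr(frames[[1L]], "tile_px"))
  if (is.null(times)) {
    times <- vapply(frames, function(f) {
      ts <- attr(f, "timestamp"); if (is.null(ts)) NA_real_ else ts
    }, numeric(1L))
    if (anyNA(times)) times <- seq_along(frames) - 1
  }
  out <- data.frame(time_s = times, gamma_mean = NA_real_, gamma_sd = NA_real_,
                    n_valid = 0L)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!all(dim(f) == dims)) stop("frames have inconsistent shapes")
    v <- f[mask]
    v <- v[is.finite(v)]
    out$n_valid[k] <- length(v)
    if (length(v) > 0L) {
      out$gamma_mean[k] <- mean(v)
      out$gamma_sd[k] <- stats::sd(v)
    }
  }
  if (any(out$n_valid == 0L))
    warning("some frames had no valid ROI pixels; gaps flagged as NA")
  class(out) <- c("gamma_series", class(out))
  out
}

#' Difference image between two stabilized states
#'
#' Pixelwise mean over the second state window minus mean over the first,
#' optionally Gaussian-smoothed, with the spatial mean and spread of the
#' difference attached.
#'
#' @param state1,state2 Lists of `gamma_frame` objects (the stabilized
#'   windows to compare).
#' @param sigma_px Smoothing sigma in pixels applied to the difference
#'   (0 = none; default half a tile when tile metadata is present, else 0).
#' @return A matrix of class `gamma_frame` with attributes `delta_mean`
#'   and `delta_sd`.
#' @export
difference_map <- function(state1, state2, sigma_px = NULL) {
  stopifnot(is.list(state1), length(state1) > 0L,
            is.list(state2), length(state2) > 0L)
  dims <- dim(state1[[1L]])
  mean_state <- function(frames) {
    acc <- matrix(0, dims[1L], dims[2L]); cnt <- acc
    for (f in frames) {
      if (!all(dim(f) == dims)) stop("state frames have mismatched shapes")
      ok <- is.finite(f)
      acc[ok] <- acc[ok] + f[ok]
      cnt[ok] <- cnt[ok] + 1
    }
    out <- matrix(NA_real_, dims[1L], dims[2L])
    out[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
    out
  }
  delta <- mean_state(state2) - mean_state(state1)
  tp <- attr(state1[[1L]], "tile_px")
  if (is.null(sigma_px)) sigma_px <- if (!is.null(tp)) tp / 2 else 0
  if (sigma_px > 0) delta <- gauss_smooth_masked(delta, sigma_px)
  structure(delta, class = c("gamma_frame", class(delta)),
            tile_px = tp,
            delta_mean = mean(delta, na.rm = TRUE),
            delta_sd = stats::sd(delta[is.finite(delta)]))
}
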