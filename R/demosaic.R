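# Pixel-shift demosaicing: split a checkerboard DBSI frame into
# co-registered narrow-band (A) and wide-band (AB) images.

# shift a matrix by (dr, dc) pixels, padding with NA
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  src_r <- seq_len(nr) + dr; src_c <- seq_len(nc) + dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

frame_tile_px <- function(frame, tile_px) {
  if (!is.null(tile_px)) return(as.integer(tile_px))
  geom <- attr(frame, "geometry")
  if (is.null(geom)) stop("`tile_px` must be given when the frame carries no geometry")
  geom$tile_px
}

#' Detect the checkerboard phase of the narrow filter
#'
#' The narrow A filter transmits less light than the wide AB filter, so the
#' checkerboard phase with the lower mean intensity is classified as A.
#'
#' @param frame A numeric matrix (optionally a `dbsi_frame`).
#' @param tile_px Pixels per tile side; taken from the frame's geometry
#'   metadata when omitted.
#' @param min_contrast Minimum relative mean difference between the two
#'   phases; below this the parity is ambiguous and an error is thrown.
#' @return Parity (0 or 1) with attribute `confidence`, the relative mean
#'   difference between the two phases.
#' @export
detect_parity <- function(frame, tile_px = NULL, min_contrast = 0.02) {
  tile_px <- frame_tile_px(frame, tile_px)
  if (nrow(frame) %% tile_px != 0L || ncol(frame) %% tile_px != 0L)
    stop("frame dimensions are not divisible by `tile_px`")
  geom0 <- mosaic_geometry(ncol(frame) / tile_px, nrow(frame) / tile_px,
                           tile_px, parity = 0)
  phase0 <- pixel_class_map(geom0)  # tiles with (i + j) even
  m0 <- mean(frame[phase0]); m1 <- mean(frame[!phase0])
  conf <- abs(m0 - m1) / mean(frame)
  if (!is.finite(conf) || conf < min_contrast)
    stop(sprintf("ambiguous parity: relative phase contrast %.3g below floor %.3g",
                 conf, min_contrast))
  parity <- if (m0 < m1) 0L else 1L
  structure(parity, confidence = conf)
}

#' Pixel-shift demosaicing of a DBSI frame
#'
#' Every pixel keeps its own value for the band its tile carries; the other
#' band is filled from the neighbouring tiles one tile pitch away. Shifting
#' by `tile_px` pixels along either image axis always lands on the opposite
#' checkerboard class, so the in-bounds shifted values (up/down/left/right)
#' are averaged by default; single-direction fills are available for
#' comparison. By default one tile is cropped from each border so every
#' output pixel has a full neighbour set.
#'
#' @param frame Numeric matrix (optionally a `dbsi_frame`).
#' @param tile_px Pixels per tile side (from frame metadata when omitted).
#' @param parity A-filter checkerboard phase; auto-detected when `NULL`.
#' @param fill Which shifted neighbours to combine: `"average"` (all
#'   in-bounds of the four), `"vertical"` or `"horizontal"`.
#' @param border `"crop"` (default) trims one tile on each side;
#'   `"none"` keeps the full frame, using whichever neighbours exist.
#' @return An object of class `band_images`: list with matrices `I_A` and
#'   `I_AB` (equal shape, co-registered), and registration metadata
#'   `tile_px`, `parity`, `crop_px`, plus `bit_depth`/`timestamp` carried
#'   over from the frame when present.
#' @export
demosaic_frame <- function(frame, tile_px = NULL, parity = NULL,
                           fill = c("average", "vertical", "horizontal"),
                           border = c("crop", "none")) {
  fill <- match.arg(fill)
  border <- match.arg(border)
  tile_px <- frame_tile_px(frame, tile_px)
  geom_attr <- attr(frame, "geometry")
  if (!is.null(geom_attr) && geom_attr$tile_px != tile_px)
    stop("`tile_px` disagrees with the frame's geometry metadata")
  if (nrow(frame) %% tile_px != 0L || ncol(frame) %% tile_px != 0L)
    stop("frame dimensions are not divisible by `tile_px`")
  if (is.null(parity)) parity <- as.integer(detect_parity(frame, tile_px))
  m <- unclass(frame); attributes(m) <- list(dim = dim(frame))

  geom <- mosaic_geometry(ncol(m) / tile_px, nrow(m) / tile_px, tile_px, parity)
  isA <- pixel_class_map(geom)

  offs <- switch(fill,
                 average = list(c(-tile_px, 0L), c(tile_px, 0L), c(0L, -tile_px), c(0L, tile_px)),
                 vertical = list(c(-tile_px, 0L), c(tile_px, 0L)),
                 horizontal = list(c(0L, -tile_px), c(0L, tile_px)))
  acc <- matrix(0, nrow(m), ncol(m)); cnt <- matrix(0, nrow(m), ncol(m))
  for (o in offs) {
    s <- shift_matrix(m, o[1L], o[2L])
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  if (any(cnt == 0))
    stop("some pixels have no in-bounds neighbour at one tile pitch; need >= 2 tiles per axis")
  filled <- acc / cnt

  I_A <- ifelse(isA, m, filled)
  I_AB <- ifelse(isA, filled, m)

  crop <- if (border == "crop") tile_px else 0L
  if (crop > 0L) {
    if (nrow(m) - 2L * crop < 1L || ncol(m) - 2L * crop < 1L)
      stop("frame too small to crop one tile per side")
    keep_r <- (crop + 1L):(nrow(m) - crop)
    keep_c <- (crop + 1L):(ncol(m) - crop)
    I_A <- I_A[keep_r, keep_c, drop = FALSE]
    I_AB <- I_AB[keep_r, keep_c, drop = FALSE]
  }
  structure(
    list(I_A = I_A, I_AB = I_AB, tile_px = tile_px, parity = as.integer(parity),
         crop_px = crop,
         bit_depth = attr(frame, "bit_depth"),
         timestamp = attr(frame, "timestamp")),
    class = "band_images")
}

#' @export
print.band_images <- function(x, ...) {
  cat(sprintf("<band_images> %d x %d px (tile_px %d, parity %d, crop %d px)\n",
              nrow(x$I_A), ncol(x$I_A), x$tile_px, x$parity, x$crop_px))
  invisible(x)
}

#' Re-interleave band images into a checkerboard frame
#'
#' Inverse of the demosaicing shift rule for noiseless data: each pixel
#' takes the band value of its own tile class. Used for round-trip checks.
#'
#' @param bands A `band_images` object (uncropped, `border = "none"`).
#' @return A numeric matrix.
#' @export
remosaic_frame <- function(bands) {
  stopifnot(inherits(bands, "band_images"))
  geom <- mosaic_geometry(ncol(bands$I_A) / bands$tile_px,
                          nrow(bands$I_A) / bands$tile_px,
                          bands$tile_px, bands$parity)
  isA <- pixel_class_map(geom)
  ifelse(isA, bands$I_A, bands$I_AB)
}
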