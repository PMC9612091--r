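# Three-phase demodulation, reflectance calibration and drift correction.

#' Demodulate three phase-shifted sinusoidal frames to an AC amplitude image
#'
#' Pixel-wise
#' `sqrt(2)/3 * sqrt((I1-I2)^2 + (I2-I3)^2 + (I3-I1)^2)`.
#' For frames `I_k = offset + amp * cos(theta + phi_k)` with phases shifted
#' by 120 degrees, this recovers `amp` exactly for any offset and `theta`.
#' The prefactor is a pure convention: it cancels in the subsequent
#' reference-phantom calibration.
#'
#' @param i1,i2,i3 images (matrices) at the three pattern phases, equal
#'   shape, finite.
#' @return Non-negative amplitude image, same shape.
#' @export
demodulate_ac <- function(i1, i2, i3) {
  if (!identical(dim(i1), dim(i2)) || !identical(dim(i2), dim(i3)))
    stop("phase frames must share shape")
  if (any(!is.finite(i1)) || any(!is.finite(i2)) || any(!is.finite(i3)))
    stop("phase frames must be finite")
  sqrt(2) / 3 * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i3 - i1)^2)
}

#' Demodulate planar (fx = 0) illumination from white and black frames
#'
#' `white - black`, floored at zero; the black frame serves as the
#' dark/ambient reference.
#'
#' @param white,black images of equal shape.
#' @return Non-negative DC image.
#' @export
demodulate_dc <- function(white, black) {
  if (!identical(dim(white), dim(black)))
    stop("white and black frames must share shape")
  pmax(white - black, 0)
}

#' Calibrate a demodulated image to diffuse reflectance
#'
#' `Rd = (I_sample / I_ref) * Rd_ref_pred`, where `Rd_ref_pred` is the
#' model-predicted diffuse reflectance of the reference phantom at the same
#' wavelength and spatial frequency (see [rd_forward()]). Pixels where the
#' reference is zero or negative are masked to `NA` and counted in the
#' `"n_masked"` attribute.
#'
#' @param i_sample,i_ref demodulated sample and reference images, equal
#'   shape.
#' @param rd_ref_pred predicted reference reflectance, scalar in (0, 1) or
#'   image of the same shape.
#' @return Reflectance image; attribute `n_masked` counts masked pixels.
#' @export
calibrate <- function(i_sample, i_ref, rd_ref_pred) {
  if (!identical(dim(i_sample), dim(i_ref)))
    stop("sample and reference images must share shape")
  if (any(rd_ref_pred <= 0) || any(rd_ref_pred >= 1))
    stop("rd_ref_pred must lie in (0, 1)")
  bad <- !(i_ref > 0)
  if (all(bad)) stop("all reference pixels are non-positive")
  rd <- i_sample / i_ref * rd_ref_pred
  rd[bad] <- NA_real_
  attr(rd, "n_masked") <- sum(bad)
  rd
}

#' Correct a reflectance time series for source drift using an in-FOV tile
#'
#' A small reference tile of stable optical properties kept in the
#' field-of-view tracks slow drift of the illumination. Each time point is
#' rescaled by `mean(tile at baseline) / mean(tile at t)`, so the tile mean
#' after correction equals its baseline mean exactly and any global
#' multiplicative drift is removed.
#'
#' @param rd_series reflectance time series: array `[H, W, T]` or list of
#'   matrices.
#' @param tile_roi tile region: `c(row1, row2, col1, col2)` (inclusive pixel
#'   bounds) or a logical mask matrix.
#' @param baseline_index time index serving as the drift-free baseline
#'   (default 1).
#' @return Corrected series in the input's form; attribute `factors` holds
#'   the per-time-point correction factors.
#' @export
drift_correct <- function(rd_series, tile_roi, baseline_index = 1L) {
  as_list <- is.list(rd_series)
  frames <- if (as_list) rd_series else
    lapply(seq_len(dim(rd_series)[3]), function(t) rd_series[, , t])
  if (baseline_index < 1 || baseline_index > length(frames))
    stop("baseline_index outside the series")
  d <- dim(frames[[1]])
  mask <- if (is.matrix(tile_roi) && is.logical(tile_roi)) tile_roi else {
    if (length(tile_roi) != 4) stop("tile_roi must be c(row1,row2,col1,col2)")
    if (tile_roi[1] < 1 || tile_roi[2] > d[1] ||
        tile_roi[3] < 1 || tile_roi[4] > d[2])
      stop("tile_roi extends outside the frames")
    m <- matrix(FALSE, d[1], d[2])
    m[tile_roi[1]:tile_roi[2], tile_roi[3]:tile_roi[4]] <- TRUE
    m
  }
  means <- vapply(frames, function(f) mean(f[mask]), 0)
  if (any(!is.finite(means)) || any(means <= 0))
    stop("tile mean must be positive and finite at every time point")
  factors <- means[baseline_index] / means
  out <- Map(function(f, g) f * g, frames, as.list(factors))
  res <- if (as_list) out else
    array(unlist(out), dim = c(d, length(frames)))
  attr(res, "factors") <- factors
  res
}
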