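# Thermal dosimetry: cumulative equivalent minutes at 43 degrees C
# (Sapareto-Dewey), lesion masks/volumes and time-to-threshold maps.

#' Accumulate CEM43 thermal dose
#'
#' Sapareto-Dewey cumulative equivalent minutes at 43 degrees C:
#' \deqn{CEM_{43}(t) = \sum_{frames \le t} R^{43 - T} \, \Delta t_{min}}
#' with `R = r_above` (0.5) for `T >= 43` and `r_below` (0.25) otherwise,
#' where `T = baseline_temp + dT` is the absolute temperature. A voxel-frame
#' with undefined temperature (`NA`, e.g. out-of-bounds after warping)
#' contributes zero dose; the per-voxel fraction of valid frames is
#' reported.
#'
#' @param temperature A [temperature_series()] or a 4D array of temperature
#'   change `[row, col, slice, frame]` in degrees C.
#' @param baseline_temp Absolute baseline temperature, degrees C
#'   (default 37).
#' @param frame_interval Seconds per frame: scalar or per-frame vector.
#' @param r_below,r_above Sapareto R constants below/above the 43 degree
#'   breakpoint (defaults 0.25 / 0.5).
#' @return Object of class `dose_map`: `cem43` (4D cumulative dose history,
#'   minutes), `valid_fraction` (3D), `frame_interval`, `baseline_temp`.
#' @export
accumulate_cem43 <- function(temperature, baseline_temp = 37,
                             frame_interval, r_below = 0.25,
                             r_above = 0.5) {
  dT <- if (inherits(temperature, "temperature_series")) {
    temperature$delta_t
  } else {
    as_4d(temperature)
  }
  d <- dim(dT)
  nt <- d[4]
  dt_s <- if (length(frame_interval) == 1) rep(frame_interval, nt) else
    frame_interval
  if (length(dt_s) != nt) {
    stop(sprintf("frame_interval must be scalar or length %d", nt),
         call. = FALSE)
  }
  if (any(dt_s < 0)) stop("negative frame interval", call. = FALSE)
  Tabs <- baseline_temp + dT
  R <- ifelse(Tabs >= 43, r_above, r_below)
  incr <- R^(43 - Tabs)
  invalid <- !is.finite(incr)
  incr[invalid] <- 0
  m <- matrix(incr, ncol = nt)
  for (t in seq_len(nt)) m[, t] <- m[, t] * (dt_s[t] / 60)
  for (t in seq_len(nt)[-1]) m[, t] <- m[, t] + m[, t - 1]
  valid_fraction <- array(rowMeans(matrix(!invalid, ncol = nt)), d[1:3])
  structure(list(cem43 = array(m, d), valid_fraction = valid_fraction,
                 frame_interval = dt_s, baseline_temp = baseline_temp),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  d <- dim(x$cem43)
  final <- x$cem43[, , , d[4]]
  cat(sprintf(
    "dose_map: %d x %d x %d voxels over %d frames, max CEM43 = %.3g min, %d voxel(s) >= 240 min\n",
    d[1], d[2], d[3], d[4], max(final), sum(final >= 240)))
  invisible(x)
}

#' Lesion mask from a dose map
#'
#' @param dose A [accumulate_cem43()] result.
#' @param threshold CEM43 lethal threshold in minutes (default 240, the
#'   standard cell-death threshold).
#' @param frame Frame at which to evaluate (default last).
#' @return Logical 3D array.
#' @export
lesion_mask <- function(dose, threshold = 240, frame = NULL) {
  nt <- dim(dose$cem43)[4]
  if (is.null(frame)) frame <- nt
  dose$cem43[, , , frame] >= threshold
}

#' Lesion volume in cubic centimetres
#'
#' Counts voxels whose cumulative CEM43 reaches `threshold` and multiplies
#' by the voxel volume.
#'
#' @param dose A [accumulate_cem43()] result.
#' @param threshold CEM43 threshold in minutes (default 240).
#' @param voxel_spacing Voxel size in mm (row, col, slice).
#' @param frame Frame at which to evaluate (default last).
#' @return Volume in cm^3.
#' @export
lesion_volume <- function(dose, threshold = 240,
                          voxel_spacing = c(1, 1, 1), frame = NULL) {
  n <- sum(lesion_mask(dose, threshold, frame))
  n * prod(voxel_spacing) / 1000
}

#' Lesion volume time series
#'
#' @inheritParams lesion_volume
#' @param frames Frames to evaluate (default all).
#' @return Numeric vector of volumes in cm^3, one per frame.
#' @export
lesion_volume_series <- function(dose, threshold = 240,
                                 voxel_spacing = c(1, 1, 1),
                                 frames = NULL) {
  nt <- dim(dose$cem43)[4]
  if (is.null(frames)) frames <- seq_len(nt)
  vapply(frames, function(t) lesion_volume(dose, threshold, voxel_spacing, t),
         0)
}

#' Time (frame index) to reach the dose threshold
#'
#' First frame at which the cumulative CEM43 reaches `threshold`; `NA` for
#' voxels that never reach it.
#'
#' @param dose A [accumulate_cem43()] result.
#' @param threshold CEM43 threshold in minutes (default 240).
#' @return Integer 3D array of frame indices (`NA` = never reached).
#' @export
time_to_threshold <- function(dose, threshold = 240) {
  d <- dim(dose$cem43)
  nt <- d[4]
  m <- matrix(dose$cem43, ncol = nt) >= threshold
  idx <- apply(m, 1, function(r) {
    w <- which(r)
    if (length(w)) w[1] else NA_integer_
  })
  array(as.integer(idx), d[1:3])
}

#' Pairwise difference of time-to-threshold maps
#'
#' `map_a - map_b` where both are defined, `NA` elsewhere. Positive values
#' mean method A reaches the lethal dose later (a delay).
#'
#' @param map_a,map_b Maps from [time_to_threshold()].
#' @return Numeric 3D array.
#' @export
time_to_threshold_diff <- function(map_a, map_b) {
  stopifnot_same_dim(map_a, map_b, "time-to-threshold maps")
  out <- map_a - map_b
  out[is.na(map_a) | is.na(map_b)] <- NA_real_
  out
}
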