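# PRF-shift thermometry: phase-difference to temperature conversion,
# temporal phase unwrapping, spatial drift correction and causal temporal
# low-pass filtering.

#' PRF thermometry parameters
#'
#' The PRF phase-temperature relation in radians is
#' \deqn{\Delta\phi = 2\pi \gamma \sigma \, TE \, B_0 \, \Delta T}
#' with \eqn{\gamma} in Hz/T. Note the \eqn{2\pi}: it is required for
#' dimensional consistency when phase is measured in radians and the
#' gyromagnetic ratio in Hz/T. With the defaults (TE = 18 ms, 1.5 T,
#' \eqn{\sigma = -0.0094} ppm/degC) one radian of phase difference
#' corresponds to about -14.7 degrees C, so heating lowers the phase.
#'
#' @param gamma Gyromagnetic ratio in Hz/T (default 42.58e6).
#' @param sigma PRF temperature coefficient in ppm per degree C
#'   (default -0.0094; must be negative).
#' @param te Echo time in seconds (default 0.018).
#' @param b0 Field strength in tesla (default 1.5).
#' @param baseline_temp Body baseline temperature in degrees C (default 37).
#' @return Object of class `thermo_params`.
#' @export
thermo_params <- function(gamma = 42.58e6, sigma = -0.0094, te = 0.018,
                          b0 = 1.5, baseline_temp = 37) {
  if (te <= 0) stop("te must be > 0", call. = FALSE)
  if (b0 <= 0) stop("b0 must be > 0", call. = FALSE)
  if (sigma >= 0) stop("sigma must be negative (PRF coefficient)",
                       call. = FALSE)
  structure(list(gamma = gamma, sigma = sigma, te = te, b0 = b0,
                 baseline_temp = baseline_temp), class = "thermo_params")
}

#' Phase per degree: the forward PRF factor
#'
#' Returns \eqn{2\pi \gamma \sigma TE B_0} in radians per degree C
#' (negative). Its reciprocal converts a phase difference to a temperature
#' change.
#'
#' @param params A [thermo_params()].
#' @return Scalar, radians per degree C.
#' @export
prf_phase_factor <- function(params = thermo_params()) {
  2 * pi * params$gamma * params$sigma * 1e-6 * params$te * params$b0
}

#' Convert a phase difference to temperature change
#'
#' \eqn{\Delta T = \mathrm{wrap}(\phi_t - \phi_{ref}) /
#' (2\pi\gamma\sigma TE B_0)}. The wrap restricts the difference to one
#' phase cycle; use [temporal_unwrap()] upstream when heating exceeds the
#' wrap limit (about 46 degrees C at the default parameters).
#'
#' @param phase_t,phase_ref Phase stacks in radians on the same grid.
#' @param params A [thermo_params()].
#' @param wrap If `FALSE` the difference is assumed already unwrapped.
#' @return Temperature change in degrees C, same shape as the input.
#' @export
phase_to_temperature <- function(phase_t, phase_ref,
                                 params = thermo_params(), wrap = TRUE) {
  stopifnot_same_dim(phase_t, phase_ref, "phase_t and phase_ref")
  d <- phase_t - phase_ref
  if (wrap) d <- wrap_phase(d)
  d / prf_phase_factor(params)
}

#' Temperature series container
#'
#' @param delta_t 4D array `[row, col, slice, frame]` of temperature change
#'   in degrees C.
#' @param valid_mask Logical array of the same shape; `FALSE` marks voxels
#'   whose value is undefined (e.g. out-of-bounds after warping). Defaults
#'   to `is.finite(delta_t)`.
#' @param params The [thermo_params()] used.
#' @param timestamps Optional per-frame acquisition times in seconds.
#' @return Object of class `temperature_series`.
#' @export
temperature_series <- function(delta_t, valid_mask = NULL,
                               params = thermo_params(),
                               timestamps = NULL) {
  delta_t <- as_4d(delta_t)
  if (is.null(valid_mask)) valid_mask <- is.finite(delta_t)
  structure(list(delta_t = delta_t, valid_mask = valid_mask,
                 params = params, timestamps = timestamps),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  d <- dim(x$delta_t)
  cat(sprintf(
    "temperature_series: %d x %d x %d voxels, %d frames, max dT = %.1f degC\n",
    d[1], d[2], d[3], d[4], max(x$delta_t, na.rm = TRUE)))
  invisible(x)
}

#' Temporally unwrap a per-voxel phase series
#'
#' Adds multiples of \eqn{2\pi} so that consecutive per-voxel differences
#' never exceed \eqn{\pi} in magnitude. Valid whenever the true
#' frame-to-frame phase change stays below \eqn{\pi} (guaranteed by the
#' acquisition frame rate relative to the heating rate).
#'
#' @param dphase Numeric array with time as the last dimension (vector,
#'   voxel-by-frame matrix, or 4D stack).
#' @return Unwrapped array of the same shape.
#' @export
temporal_unwrap <- function(dphase) {
  d <- dim(dphase)
  if (is.null(d)) {
    dp <- diff(dphase)
    return(c(dphase[1], dphase[1] + cumsum(wrap_phase(dp))))
  }
  nt <- d[length(d)]
  m <- matrix(dphase, ncol = nt)
  out <- m
  for (t in 2:nt) {
    out[, t] <- out[, t - 1] + wrap_phase(m[, t] - m[, t - 1])
  }
  array(out, d)
}

#' Cumulative heated-voxel mask
#'
#' Marks voxels whose temperature change exceeded `threshold` degrees C at
#' the given frame or any earlier frame; those voxels are excluded from the
#' drift-correction fit.
#'
#' @param delta_t 4D temperature array.
#' @param threshold Exclusion threshold in degrees C (default 3).
#' @return Logical 4D array (cumulative over frames).
#' @export
cumulative_heated_mask <- function(delta_t, threshold = 3) {
  d <- dim(delta_t)
  hot <- abs(delta_t) > threshold
  hot[is.na(hot)] <- FALSE
  nt <- d[4]
  if (nt > 1) {
    m <- matrix(hot, ncol = nt)
    for (t in 2:nt) m[, t] <- m[, t] | m[, t - 1]
    hot <- array(m, d)
  }
  hot
}

#' Remove slow spatial-temporal phase drift from temperature maps
#'
#' Per frame and per slice, fits a first-order 2D spatial polynomial
#' (`1 + row + col`) to the temperature of unheated in-body voxels and
#' subtracts the fitted surface everywhere in the slice. This removes both
#' spatially uniform drift and smooth first-order field drift without
#' touching the heating signal (heated voxels are excluded from the fit).
#'
#' @param delta_t 4D temperature array `[row, col, slice, frame]`.
#' @param heated_mask Logical array, same shape (or 3D, applied to every
#'   frame): voxels excluded from the drift fit. See
#'   [cumulative_heated_mask()].
#' @param body_mask Optional logical 3D array restricting the fit to tissue.
#' @param min_voxels Minimum unheated voxels required per slice to fit
#'   (default 50); below this the slice/frame is left untouched with a
#'   warning.
#' @return Drift-corrected array of the same shape.
#' @export
drift_correct <- function(delta_t, heated_mask = NULL, body_mask = NULL,
                          min_voxels = 50L) {
  delta_t <- as_4d(delta_t)
  d <- dim(delta_t)
  if (is.null(heated_mask)) heated_mask <- array(FALSE, d)
  if (length(dim(heated_mask)) == 3) {
    heated_mask <- array(heated_mask, d)
  }
  if (is.null(body_mask)) body_mask <- array(TRUE, d[1:3])
  rr <- matrix(seq_len(d[1]), d[1], d[2]) / d[1]
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) / d[2]
  X <- cbind(1, as.vector(rr), as.vector(cc))
  skipped <- 0L
  out <- delta_t
  for (t in seq_len(d[4])) {
    for (s in seq_len(d[3])) {
      sl <- delta_t[, , s, t]
      use <- body_mask[, , s] & !heated_mask[, , s, t] & is.finite(sl)
      if (sum(use) < min_voxels) {
        skipped <- skipped + 1L
        next
      }
      fit <- stats::lm.fit(X[use, , drop = FALSE], sl[use])
      surf <- matrix(X %*% fit$coefficients, d[1], d[2])
      out[, , s, t] <- sl - surf
    }
  }
  if (skipped > 0L) {
    warning(sprintf(
      "drift correction skipped for %d slice-frame(s): fewer than %d unheated voxels",
      skipped, min_voxels))
  }
  out
}

#' Causal first-order Butterworth low-pass filter along time
#'
#' Applies a first-order digital Butterworth low-pass (bilinear transform,
#' cutoff prewarped so the half-power point sits exactly at `cutoff`)
#' causally along the last (time) dimension of the input: the output at
#' frame `t` depends only on frames `<= t`, as required for real-time
#' display. Gated series with irregular timestamps use the mean frame
#' interval for the filter coefficient.
#'
#' @param x Numeric vector, voxel-by-frame matrix or 4D stack; time last.
#' @param cutoff Cutoff frequency in Hz (default 0.14).
#' @param frame_interval Seconds between frames (scalar, or per-frame vector
#'   whose mean is used).
#' @return Filtered array of the same shape.
#' @export
lowpass_filter <- function(x, cutoff = 0.14, frame_interval) {
  fi <- mean(frame_interval)
  nyquist <- 1 / (2 * fi)
  if (cutoff >= nyquist) {
    stop(sprintf("cutoff %.3g Hz is at or above Nyquist (%.3g Hz)",
                 cutoff, nyquist), call. = FALSE)
  }
  bf <- signal::butter(1, cutoff / nyquist, type = "low")
  b <- bf$b; a <- bf$a
  d <- dim(x)
  if (is.null(d)) {
    m <- matrix(x, nrow = 1)
  } else {
    m <- matrix(x, ncol = d[length(d)])
  }
  nt <- ncol(m)
  out <- m
  out[, 1] <- b[1] * m[, 1]
  if (nt > 1) {
    for (t in 2:nt) {
      out[, t] <- b[1] * m[, t] + b[2] * m[, t - 1] - a[2] * out[, t - 1]
    }
  }
  if (is.null(d)) as.vector(out) else array(out, d)
}
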