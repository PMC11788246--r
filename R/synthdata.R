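# Synthetic dynamic abdominal phantom with known ground truth.
#
# The generator emulates the acquisition regimes of MR-guided thermal
# ablation of the liver: periodic respiratory displacement of a few voxels,
# gated vs fixed-frequency (0.5 Hz) sampling, motion-coupled background
# (susceptibility) phase, a heating hotspot obeying the PRF relation with
# strong magnitude signal dropout around the applicator, complex Gaussian
# noise and slow phase drift. Everything is generated in "material"
# (tissue) coordinates and then deformed per frame, so the exact deforming
# field, temperature and lesion extent are available as ground truth.

#' Phantom configuration
#'
#' @param grid Integer length-3 `(n_rows, n_cols, n_slices)`.
#' @param n_frames Number of dynamic frames (>= 20: the pipeline's 15-frame
#'   learning phase must fit before the intervention).
#' @param frame_interval Nominal seconds between frames (2 s = 0.5 Hz for the
#'   fixed-frequency regime; one respiratory period for gating).
#' @param mode `"fixed_frequency"` (samples the whole breathing cycle) or
#'   `"gated"` (samples near end-exhale with a small positional jitter).
#' @param respiratory_period Breathing period in seconds (default 4.5 s,
#'   ventilated patient under general anesthesia, about half the 2 s frame
#'   interval rate).
#' @param displacement_amplitude Peak head-foot displacement in voxels
#'   (default 4; clinically ~4-5 voxels).
#' @param gating_jitter SD of the residual per-frame displacement in gated
#'   mode, voxels (default 0.2).
#' @param hotspot_center Voxel coords `(row, col, slice)` of the heating
#'   focus; default grid centre.
#' @param hotspot_sigma In-plane Gaussian width of the hotspot, voxels.
#' @param peak_delta_t Peak temperature rise in degrees C (default 50).
#' @param heating_window Integer `(start_frame, end_frame)` of energy
#'   delivery, 1-based inclusive.
#' @param max_signal_drop Peak fractional magnitude loss in the hotspot
#'   during heating, in `[0, 1]` (default 0.5).
#' @param susceptibility_gain Motion-coupled background phase, radians per
#'   voxel of local displacement (default 0.05).
#' @param noise_sd SD of the additive complex Gaussian noise as a fraction of
#'   the peak baseline magnitude (default 0.02).
#' @param drift_rate Spatially uniform phase drift in rad/frame
#'   (default 0.002).
#' @param voxel_spacing Voxel size in mm (row, col, slice); default
#'   `c(2.5, 2.5, 3)`.
#' @param te,b0 Echo time (s) and field strength (T) used for the forward
#'   PRF phase; defaults 18 ms and 1.5 T.
#' @param seed Integer RNG seed; the same seed gives bit-identical series.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(64L, 64L, 3L), n_frames = 60L,
                           frame_interval = 2,
                           mode = c("fixed_frequency", "gated"),
                           respiratory_period = 4.5,
                           displacement_amplitude = 4,
                           gating_jitter = 0.2,
                           hotspot_center = NULL,
                           hotspot_sigma = 3,
                           peak_delta_t = 50,
                           heating_window = NULL,
                           max_signal_drop = 0.5,
                           susceptibility_gain = 0.05,
                           noise_sd = 0.02,
                           drift_rate = 0.002,
                           voxel_spacing = c(2.5, 2.5, 3),
                           te = 0.018, b0 = 1.5,
                           seed = 42L) {
  mode <- match.arg(mode)
  grid <- as.integer(grid)
  n_frames <- as.integer(n_frames)
  if (n_frames < 20L) {
    stop("n_frames must be >= 20 (15 learning frames + intervention)",
         call. = FALSE)
  }
  if (max_signal_drop < 0 || max_signal_drop > 1) {
    stop("max_signal_drop must lie in [0, 1]", call. = FALSE)
  }
  if (displacement_amplitude < 0) {
    stop("displacement_amplitude must be >= 0", call. = FALSE)
  }
  if (is.null(hotspot_center)) {
    hotspot_center <- c(round(grid[1] / 2), round(grid[2] / 2),
                        ceiling(grid[3] / 2))
  }
  if (is.null(heating_window)) {
    heating_window <- c(16L, max(20L, round(0.75 * n_frames)))
  }
  heating_window <- as.integer(heating_window)
  if (heating_window[1] < 1L || heating_window[2] > n_frames ||
      heating_window[1] >= heating_window[2]) {
    stop(sprintf("heating_window [%d, %d] must lie within [1, %d]",
                 heating_window[1], heating_window[2], n_frames),
         call. = FALSE)
  }
  structure(list(
    grid = grid, n_frames = n_frames, frame_interval = frame_interval,
    mode = mode, respiratory_period = respiratory_period,
    displacement_amplitude = displacement_amplitude,
    gating_jitter = gating_jitter, hotspot_center = hotspot_center,
    hotspot_sigma = hotspot_sigma, peak_delta_t = peak_delta_t,
    heating_window = heating_window, max_signal_drop = max_signal_drop,
    susceptibility_gain = susceptibility_gain, noise_sd = noise_sd,
    drift_rate = drift_rate, voxel_spacing = voxel_spacing,
    te = te, b0 = b0, seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Acquisition-regime presets
#'
#' `"gated_paper"`: respiratory-gated regime — one frame per breathing cycle
#' (4 s interval), 13 slices of 128 x 128 voxels, near-zero inter-frame
#' motion (0.2-voxel gating jitter). `"fixed_frequency_paper"`:
#' continuous 0.5 Hz sampling (2.0 s interval), 13 slices, 4.5-voxel
#' breathing displacement. Both heat to a peak of +50 degrees C with 50%
#' peak magnitude signal loss around the applicator.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [phantom_config()].
#' @return A [phantom_config()].
#' @export
preset_config <- function(name = c("gated_paper", "fixed_frequency_paper"),
                          ...) {
  presets <- c("gated_paper", "fixed_frequency_paper")
  if (!is.character(name) || !(name[1] %in% presets)) {
    stop(sprintf("unknown preset '%s'; available presets: %s",
                 as.character(name)[1], paste(presets, collapse = ", ")),
         call. = FALSE)
  }
  name <- name[1]
  base <- if (name == "gated_paper") {
    list(grid = c(128L, 128L, 13L), n_frames = 180L, frame_interval = 4.0,
         mode = "gated", displacement_amplitude = 0,
         gating_jitter = 0.2, peak_delta_t = 50, max_signal_drop = 0.5,
         heating_window = c(16L, 151L), voxel_spacing = c(2.5, 2.5, 3))
  } else {
    list(grid = c(128L, 128L, 13L), n_frames = 350L, frame_interval = 2.0,
         mode = "fixed_frequency", displacement_amplitude = 4.5,
         peak_delta_t = 50, max_signal_drop = 0.5,
         heating_window = c(16L, 286L), voxel_spacing = c(2.5, 2.5, 3))
  }
  args <- utils::modifyList(base, list(...))
  do.call(phantom_config, args)
}

#' Respiratory displacement profile
#'
#' Normalized breathing waveform `sin(pi * t / period)^4` in `[0, 1]`: an
#' asymmetric cycle with a flat end-exhale plateau (Lujan-type model). Its
#' mean over a full cycle is exactly 3/8.
#'
#' @param t Time in seconds.
#' @param period Respiratory period in seconds.
#' @return Values in `[0, 1]`.
#' @export
resp_profile <- function(t, period) {
  sin(pi * t / period)^4
}

# liver-like template: bright elliptical parenchyma with smooth texture and
# dark vessel-like structures, on a faint background
make_template <- function(grid) {
  nr <- grid[1]; nc <- grid[2]; ns <- grid[3]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  tmpl <- array(0.05, grid)
  for (s in seq_len(ns)) {
    a <- 0.42 * nr * (1 - 0.03 * abs(s - (ns + 1) / 2))
    b <- 0.40 * nc
    body <- ((rr - nr / 2) / a)^2 + ((cc - nc / 2) / b)^2 <= 1
    # two-scale parenchymal texture: optical flow needs the gradient
    # structure real EPI liver images have
    coarse <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 3)
    fine <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 1.2)
    texture <- 0.22 * coarse / max(abs(coarse)) + 0.18 * fine / max(abs(fine))
    sl <- matrix(0.05, nr, nc)
    sl[body] <- 1 + texture[body]
    # vessel-like dark structures: smoothed dark disks of varying size
    for (vv in seq_len(6)) {
      vr <- stats::runif(1, 0.25 * nr, 0.75 * nr)
      vc <- stats::runif(1, 0.25 * nc, 0.75 * nc)
      vs <- stats::runif(1, 1.2, 3)
      dark <- exp(-((rr - vr)^2 + (cc - vc)^2) / (2 * vs^2))
      sl <- sl * (1 - 0.5 * dark)
    }
    tmpl[, , s] <- gauss_smooth(sl, 0.8)
  }
  tmpl
}

# smooth spatially varying motion envelope, peak-normalized to 1
make_motion_envelope <- function(grid) {
  nr <- grid[1]; nc <- grid[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  w <- 0.7 + 0.3 * exp(-((rr - nr / 2)^2 + (cc - nc / 2)^2) /
                         (2 * (0.4 * min(nr, nc))^2))
  env <- array(rep(w / max(w), grid[3]), grid)
  env
}

# in-plane + through-slice Gaussian hotspot, peak 1 at the centre
hotspot_shape <- function(grid, center, sigma, slice_sigma = 1.2) {
  nr <- grid[1]; nc <- grid[2]; ns <- grid[3]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inplane <- exp(-((rr - center[1])^2 + (cc - center[2])^2) / (2 * sigma^2))
  out <- array(0, grid)
  for (s in seq_len(ns)) {
    out[, , s] <- inplane * exp(-(s - center[3])^2 / (2 * slice_sigma^2))
  }
  out
}

# temporal heating envelope in [0, 1]: saturating rise during the heating
# window, exponential cooling afterwards
heating_profile <- function(frames, window, frame_interval) {
  t0 <- window[1]; t1 <- window[2]
  tau_rise <- max(1, (t1 - t0) / 3)
  tau_cool <- max(1, (t1 - t0) / 2)
  h <- numeric(length(frames))
  during <- frames >= t0 & frames <= t1
  h[during] <- 1 - exp(-(frames[during] - t0) / tau_rise)
  after <- frames > t1
  h_end <- 1 - exp(-(t1 - t0) / tau_rise)
  h[after] <- h_end * exp(-(frames[after] - t1) / tau_cool)
  h
}

#' Generate a synthetic dynamic series with ground truth
#'
#' Builds a liver-like template (smooth parenchyma with vessel-like dark
#' structures), a smooth motion envelope, and a Gaussian heating hotspot in
#' material coordinates; the phase is
#' `phi0 + susceptibility_gain * displacement + prf_phase_factor * dT +
#' drift`, the magnitude is multiplied by `(1 - drop)` inside the hotspot
#' with `drop` time-locked to the temperature rise. Each frame is the
#' pull-back deformation of the material complex image by that frame's
#' displacement field; complex Gaussian noise is added afterwards (Rician
#' magnitude statistics).
#'
#' @param config A [phantom_config()].
#' @return List with `series` (a [dynamic_series()]) and `truth`, a
#'   `ground_truth` object holding per-frame deforming fields
#'   (`displacements`, [flow_field()]s on the frame grid with
#'   `frame = warp(material, D_t)`), the scalar breathing positions `s`,
#'   the true temperature rise `delta_t` `[row, col, slice, frame]` in
#'   material coordinates, the `lesion_mask` (CEM43 >= 240 min at the last
#'   frame), the `body_mask` and the `template`.
#' @export
generate_series <- function(config) {
  with_seed(config$seed, generate_series_impl(config))
}

generate_series_impl <- function(cfg) {
  grid <- cfg$grid; nt <- cfg$n_frames
  tmpl <- make_template(grid)
  env <- make_motion_envelope(grid)
  body <- tmpl > 0.2

  # baseline (susceptibility) phase: smooth linear ramps + smooth random field
  nr <- grid[1]; nc <- grid[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  phi0 <- array(0, grid)
  ramp <- 0.6 * (rr / nr) + 0.4 * (cc / nc)
  for (s in seq_len(grid[3])) {
    bump <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 10)
    phi0[, , s] <- ramp + 0.5 * bump / max(abs(bump)) + 0.05 * s
  }

  # breathing position per frame (scalar, voxels) and timestamps
  if (cfg$mode == "fixed_frequency") {
    timestamps <- (seq_len(nt) - 1) * cfg$frame_interval
    s_t <- cfg$displacement_amplitude *
      resp_profile(timestamps, cfg$respiratory_period)
  } else {
    jit <- abs(stats::rnorm(nt, 0, cfg$gating_jitter))
    s_t <- cfg$displacement_amplitude * 0 + jit
    ts_jit <- stats::rnorm(nt, 0, 0.02 * cfg$frame_interval)
    timestamps <- (seq_len(nt) - 1) * cfg$frame_interval + ts_jit
    timestamps <- cummax(timestamps + seq_len(nt) * 1e-6)  # keep increasing
  }

  hs_temp <- hotspot_shape(grid, cfg$hotspot_center, cfg$hotspot_sigma)
  hs_drop <- hotspot_shape(grid, cfg$hotspot_center, cfg$hotspot_sigma)
  h_t <- heating_profile(seq_len(nt), cfg$heating_window, cfg$frame_interval)
  # the signal drop is time-locked to the temperature rise: no heating,
  # no dropout
  drop_scale <- if (cfg$peak_delta_t > 0) cfg$max_signal_drop else 0

  prf_fac <- prf_phase_factor(thermo_params(te = cfg$te, b0 = cfg$b0))

  mag4 <- array(0, c(grid, nt))
  pha4 <- array(0, c(grid, nt))
  dt4 <- array(0, c(grid, nt))
  disp <- vector("list", nt)
  noise_scale <- cfg$noise_sd * max(tmpl)
  bg_phase <- phi0  # phase used to fill out-of-bounds background

  for (t in seq_len(nt)) {
    dT <- cfg$peak_delta_t * h_t[t] * hs_temp
    dt4[, , , t] <- dT
    v_field <- s_t[t] * env            # head-foot (row) displacement
    u_field <- 0.15 * s_t[t] * env     # small in-plane transverse component
    D_t <- flow_field(u_field, v_field)
    disp[[t]] <- D_t
    mag_mat <- tmpl * (1 - drop_scale * h_t[t] * hs_drop)
    phi_mat <- phi0 + cfg$susceptibility_gain * v_field +
      prf_fac * dT + cfg$drift_rate * (t - 1)
    cm <- mag_mat * exp(1i * phi_mat)
    warped <- warp_image(cm, D_t)
    oob <- is.na(Re(warped))
    if (any(oob)) {
      warped[oob] <- (0.05 * exp(1i * bg_phase))[oob]
    }
    if (noise_scale > 0) {
      nvox <- prod(grid)
      warped <- warped + complex(
        real = stats::rnorm(nvox, 0, noise_scale),
        imaginary = stats::rnorm(nvox, 0, noise_scale))
    }
    mag4[, , , t] <- Mod(warped)
    pha4[, , , t] <- wrap_phase(Arg(warped))
  }

  series <- dynamic_series(mag4, pha4, timestamps,
                           voxel_spacing = cfg$voxel_spacing,
                           frame_interval = cfg$frame_interval)

  # ground-truth lesion: CEM43 through the true temperature course
  true_dose <- accumulate_cem43(dt4, baseline_temp = 37,
                                frame_interval = cfg$frame_interval)
  lesion <- true_dose$cem43[, , , nt] >= 240

  truth <- structure(list(
    displacements = disp, s = s_t, delta_t = dt4,
    lesion_mask = lesion, body_mask = body, template = tmpl,
    phi0 = phi0, heating_profile = h_t, config = cfg
  ), class = "ground_truth")
  list(series = series, truth = truth)
}

#' Ground-truth flow relative to a reference frame
#'
#' The generator stores per-frame deforming fields `D_t` with
#' `frame_t = warp(material, D_t)`. The field a registration algorithm
#' aligning frame `t` onto reference frame `r` should estimate is (to first
#' order in the envelope's spatial variation) `D_r - D_t`, on the reference
#' grid.
#'
#' @param truth `ground_truth` from [generate_series()].
#' @param t Frame index.
#' @param reference Reference frame index.
#' @return A [flow_field()].
#' @export
true_flow_to_reference <- function(truth, t, reference) {
  Dr <- truth$displacements[[reference]]
  Dt <- truth$displacements[[t]]
  flow_field(Dr$u - Dt$u, Dr$v - Dt$v)
}

#' Ground-truth temperature at the reference frame position
#'
#' True temperature maps live in material coordinates; workflow outputs live
#' on the grid of the selected reference frame. This warps the true maps by
#' the reference frame's deforming field so both are comparable voxel by
#' voxel.
#'
#' @param truth `ground_truth` from [generate_series()].
#' @param reference Reference frame index.
#' @return 4D array `[row, col, slice, frame]` of true temperature rise.
#' @export
true_temperature_at_reference <- function(truth, reference) {
  Dr <- truth$displacements[[reference]]
  out <- truth$delta_t
  if (max(abs(Dr$u), abs(Dr$v)) < 1e-9) return(out)
  for (t in seq_len(dim(out)[4])) {
    w <- warp_image(out[, , , t], Dr)
    w[is.na(w)] <- 0
    out[, , , t] <- w
  }
  out
}
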