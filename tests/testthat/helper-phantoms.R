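# Shared phantom fixtures, built once per test session and cached.
# The two workflow-comparison phantoms are the controlled experiments used
# throughout: a motionless gated series with heating-induced signal dropout
# (isolates the intensity-artifact failure mode of conventional optical
# flow) and a breathing fixed-frequency series with heating (exercises the
# full motion + susceptibility + heating chain).

.phantom_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .phantom_cache)) {
    assign(name, build(), envir = .phantom_cache)
  }
  get(name, envir = .phantom_cache)
}

# motionless, noise-free gated phantom with 50% hotspot signal dropout
gated_dropout_case <- function() {
  cached("gated_dropout", function() {
    cfg <- phantom_config(grid = c(64L, 64L, 3L), n_frames = 60L,
                          frame_interval = 4, mode = "gated",
                          displacement_amplitude = 0, gating_jitter = 0,
                          noise_sd = 0, drift_rate = 0,
                          heating_window = c(16L, 48L), peak_delta_t = 50,
                          max_signal_drop = 0.5, seed = 101L)
    gen <- generate_series(cfg)
    res <- suppressWarnings(compare_workflows(
      gen$series,
      list(standard = workflow_config("standard"),
           conventional = workflow_config("conventional_of"),
           pca = workflow_config("pca_of")),
      truth = gen$truth))
    list(gen = gen, res = res)
  })
}

# breathing phantom, 0.5 Hz sampling, 4-voxel amplitude, with heating
ff_motion_case <- function() {
  cached("ff_motion", function() {
    cfg <- phantom_config(grid = c(64L, 64L, 3L), n_frames = 70L,
                          frame_interval = 2, mode = "fixed_frequency",
                          displacement_amplitude = 4,
                          heating_window = c(16L, 55L), peak_delta_t = 50,
                          max_signal_drop = 0.5, seed = 202L)
    gen <- generate_series(cfg)
    res <- suppressWarnings(compare_workflows(
      gen$series,
      list(standard = workflow_config("standard"),
           conventional = workflow_config("conventional_of"),
           pca = workflow_config("pca_of")),
      truth = gen$truth))
    list(gen = gen, res = res)
  })
}

# small quiet template for flow/warp unit tests
quiet_template <- function(grid = c(64L, 64L, 1L), seed = 7L) {
  cached(paste0("tmpl", paste(grid, collapse = "x"), "_", seed), function() {
    cfg <- phantom_config(grid = grid, n_frames = 20L, noise_sd = 0,
                          displacement_amplitude = 0, peak_delta_t = 0,
                          drift_rate = 0, seed = seed)
    generate_series(cfg)$truth$template
  })
}

# maximum endpoint error (voxels) inside the ROI against the true motion
max_ee_vs_truth <- function(result, truth, roi, frames) {
  max(vapply(frames, function(t) {
    tf <- true_flow_to_reference(truth, t, result$reference_frame)
    ee <- endpoint_error(result$flows[[t]], tf, roi, c(1, 1))
    max(ee$ee[roi$inclusion_mask], na.rm = TRUE)
  }, 0))
}

# per-frame RMSE and bias of a workflow's temperature against ground truth
# over the ROI inclusion mask
temp_err_vs_truth <- function(result, truth, frames, roi = NULL) {
  tt <- true_temperature_at_reference(truth, result$reference_frame)
  if (is.null(roi)) roi <- make_roi(tt, truth$config$hotspot_center)
  stats <- vapply(frames, function(t) {
    err <- (result$temperature$delta_t[, , , t] - tt[, , , t])[roi$inclusion_mask]
    c(rmse = sqrt(mean(err^2, na.rm = TRUE)), bias = mean(err, na.rm = TRUE))
  }, c(rmse = 0, bias = 0))
  list(rmse = stats["rmse", ], bias = stats["bias", ])
}
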