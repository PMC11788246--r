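# End-to-end thermometry workflows:
#   standard        - fixed-reference phase subtraction, no registration
#   conventional_of - per-frame Horn-Schunck registration + susceptibility
#                     phase correction
#   pca_of          - Horn-Schunck on the 15-frame learning phase, PCA basis
#                     + susceptibility model, then PCA-constrained flow for
#                     every intervention frame
# All three share the downstream chain: temporal unwrapping, drift
# correction, causal low-pass filtering, CEM43 dose accumulation.

#' Workflow configuration
#'
#' @param method `"standard"`, `"conventional_of"` or `"pca_of"`.
#' @param learning_frames Preparative frames used to learn the motion basis
#'   and susceptibility model (default 15; the intervention runs from frame
#'   `learning_frames + 1` to the end).
#' @param reference_window Initial frames scanned for the reference position
#'   (default 10).
#' @param reference_frame Optional explicit reference frame index; when
#'   `NULL` the optical-flow workflows select it with
#'   [select_reference_frame()] and the standard workflow uses frame 1
#'   (it performs no registration).
#' @param thermometry A [thermo_params()].
#' @param flow_params Horn-Schunck parameters, see [hs_params()].
#' @param pca_params List with `n_gauss_newton`, `tolerance` for
#'   [estimate_flow_pca()].
#' @param variance_threshold,max_components PCA basis retention rule
#'   (defaults 0.95 and 5).
#' @param n_descriptors Cap on the motion descriptors driving the
#'   susceptibility model (default 3).
#' @param drift_threshold Heated-voxel exclusion threshold for the drift fit,
#'   degrees C (default 3).
#' @param drift_min_voxels Minimum unheated voxels per slice for the drift
#'   fit (default 50).
#' @param filter_cutoff Temporal low-pass cutoff in Hz (default 0.14).
#' @param dose_threshold CEM43 lethal threshold in minutes (default 240).
#' @param keep_flows Store per-frame flow fields in the result (default
#'   `TRUE`; disable for very large series).
#' @param seed Stored for provenance; the pipeline itself is deterministic.
#' @return Object of class `workflow_config`.
#' @export
workflow_config <- function(method = c("standard", "conventional_of",
                                       "pca_of"),
                            learning_frames = 15L,
                            reference_window = 10L,
                            reference_frame = NULL,
                            thermometry = thermo_params(),
                            flow_params = hs_params(),
                            pca_params = list(n_gauss_newton = 10L,
                                              tolerance = 1e-4),
                            variance_threshold = 0.95,
                            max_components = 5L,
                            n_descriptors = 3L,
                            drift_threshold = 3,
                            drift_min_voxels = 50L,
                            filter_cutoff = 0.14,
                            dose_threshold = 240,
                            keep_flows = TRUE,
                            seed = 1L) {
  method <- match.arg(method)
  learning_frames <- as.integer(learning_frames)
  reference_window <- as.integer(reference_window)
  if (learning_frames < reference_window) {
    stop("learning_frames must be >= reference_window", call. = FALSE)
  }
  structure(list(
    method = method, learning_frames = learning_frames,
    reference_window = reference_window, reference_frame = reference_frame,
    thermometry = thermometry, flow_params = flow_params,
    pca_params = pca_params, variance_threshold = variance_threshold,
    max_components = as.integer(max_components),
    n_descriptors = as.integer(n_descriptors),
    drift_threshold = drift_threshold,
    drift_min_voxels = as.integer(drift_min_voxels),
    filter_cutoff = filter_cutoff, dose_threshold = dose_threshold,
    keep_flows = isTRUE(keep_flows), seed = as.integer(seed)
  ), class = "workflow_config")
}

# body mask from the reference magnitude: tissue is bright, air is not
body_mask_from <- function(ref_mag) {
  ref_mag > 0.2 * stats::quantile(ref_mag, 0.99, na.rm = TRUE)
}

#' Run one thermometry workflow end to end
#'
#' Executes registration (per `config$method`), susceptibility phase
#' correction, PRF temperature conversion with temporal unwrapping, drift
#' correction, causal low-pass filtering and CEM43 dose accumulation.
#'
#' @param series A [dynamic_series()].
#' @param config A [workflow_config()].
#' @return List of class `workflow_result`: `temperature`
#'   (a [temperature_series()] on the reference-frame grid), `dose`
#'   (a [accumulate_cem43()] result), `reference_frame`, `basis`, `model`,
#'   `flows` (if kept), `descriptors` (frame x k matrix), `registered_magnitude`,
#'   `log` (per-frame data frame), `config`.
#' @export
run_workflow <- function(series, config = workflow_config()) {
  nt <- n_frames(series)
  L <- config$learning_frames
  if (nt <= L) {
    stop(sprintf("series has %d frames; need more than learning_frames = %d",
                 nt, L), call. = FALSE)
  }
  method <- config$method
  dims <- dim(series$magnitude)[1:3]
  fi <- series$frame_interval
  dts <- if (nt > 1) c(fi, diff(series$timestamps)) else fi

  # ---- reference position -------------------------------------------------
  ref_idx <- config$reference_frame
  if (is.null(ref_idx)) {
    ref_idx <- if (method == "standard") 1L else
      select_reference_frame(series, config$reference_window,
                             config$flow_params)
  }
  ref_mag <- as_3d(frame_stack(series$magnitude, ref_idx))
  ref_phase <- as_3d(frame_stack(series$phase, ref_idx))
  body <- body_mask_from(ref_mag)

  flows <- NULL
  basis <- NULL
  model <- NULL
  descriptors <- NULL
  reg_mag <- series$magnitude
  dphi_raw <- array(0, c(dims, nt))
  valid <- array(TRUE, c(dims, nt))

  if (method == "standard") {
    for (t in seq_len(nt)) {
      dphi_raw[, , , t] <- wrap_phase(
        as_3d(frame_stack(series$phase, t)) - ref_phase)
    }
  } else {
    # ---- registration -----------------------------------------------------
    flows <- vector("list", nt)
    for (t in seq_len(L)) {
      flows[[t]] <- estimate_flow_hs(as_3d(frame_stack(series$magnitude, t)),
                                     ref_mag, config$flow_params)
    }
    basis <- build_flow_basis(flows[seq_len(L)],
                              config$variance_threshold,
                              config$max_components)
    k_desc <- min(basis$n_retained, config$n_descriptors)
    if (method == "conventional_of") {
      for (t in (L + 1):nt) {
        flows[[t]] <- estimate_flow_hs(
          as_3d(frame_stack(series$magnitude, t)), ref_mag,
          config$flow_params)
      }
      descr_of <- function(t) project_flow(basis, flows[[t]])[seq_len(k_desc)]
    } else {
      pca_coef <- matrix(0, nt, max(basis$n_retained, 1L))
      for (t in (L + 1):nt) {
        est <- estimate_flow_pca(as_3d(frame_stack(series$magnitude, t)),
                                 ref_mag, basis, config$pca_params)
        flows[[t]] <- est$flow
        if (length(est$coefficients)) pca_coef[t, seq_along(est$coefficients)] <-
            est$coefficients
      }
      for (t in seq_len(L)) {
        pc <- project_flow(basis, flows[[t]])
        if (length(pc)) pca_coef[t, seq_along(pc)] <- pc
      }
      descr_of <- function(t) pca_coef[t, seq_len(k_desc)]
    }
    if (k_desc > 0) {
      dm <- vapply(seq_len(nt), function(t) as.numeric(descr_of(t)),
                   numeric(k_desc))
      descriptors <- if (k_desc == 1L) matrix(dm, ncol = 1) else t(dm)
    } else {
      descriptors <- matrix(0, nt, 0)
    }

    # ---- warp magnitude and phase (complex) to the reference position -----
    for (t in seq_len(nt)) {
      cm <- as_3d(frame_stack(series$magnitude, t)) *
        exp(1i * as_3d(frame_stack(series$phase, t)))
      w <- warp_image(cm, flows[[t]])
      oob <- is.na(Re(w))
      valid[, , , t] <- !oob
      w[oob] <- 0
      reg_mag[, , , t] <- Mod(w)
      dphi <- wrap_phase(Arg(w) - ref_phase)
      dphi[oob] <- 0
      dphi_raw[, , , t] <- dphi
    }

    # ---- susceptibility model on the learning phase ------------------------
    if (k_desc > 0) {
      dphi_learn <- temporal_unwrap(dphi_raw[, , , seq_len(L), drop = FALSE])
      model <- fit_susceptibility_model(dphi_learn,
                                        descriptors[seq_len(L), , drop = FALSE])
    }
  }

  # ---- temperature: unwrap, background-subtract, convert ------------------
  dphi_un <- temporal_unwrap(dphi_raw)
  if (!is.null(model)) {
    for (t in seq_len(nt)) {
      dphi_un[, , , t] <- as.vector(dphi_un[, , , t]) -
        as.vector(predict_background_phase(model, descriptors[t, ]))
    }
  }
  dT <- dphi_un / prf_phase_factor(config$thermometry)

  # ---- drift correction and causal temporal filtering ---------------------
  heated <- cumulative_heated_mask(dT, config$drift_threshold)
  dT <- drift_correct(dT, heated, body, config$drift_min_voxels)
  if (config$filter_cutoff < 0.95 / (2 * fi)) {
    dT <- lowpass_filter(dT, config$filter_cutoff, fi)
  } else {
    warning(sprintf(
      "frame interval %.3g s cannot support the %.3g Hz cutoff; temporal filtering skipped",
      fi, config$filter_cutoff))
  }

  # PRF temperature is meaningless where there is no tissue signal: mark
  # air voxels invalid so random phase cannot accumulate thermal dose
  valid <- valid & array(body, dim(valid))
  dT_out <- dT
  dT_out[!valid] <- NA_real_
  temp <- temperature_series(dT_out, valid, config$thermometry,
                             series$timestamps)
  dose <- accumulate_cem43(temp, config$thermometry$baseline_temp, dts)

  logdf <- data.frame(
    frame = seq_len(nt),
    method = method,
    flow_norm = if (is.null(flows)) 0 else
      vapply(flows, function(f) mean(sqrt(f$u^2 + f$v^2)), 0),
    mag_nrmse = vapply(seq_len(nt), function(t)
      nrmse(frame_stack(reg_mag, t), ref_mag), 0),
    intercorrelation = vapply(seq_len(nt), function(t)
      intercorrelation(frame_stack(reg_mag, t), ref_mag), 0)
  )

  structure(list(
    temperature = temp, dose = dose, reference_frame = ref_idx,
    basis = basis, model = model,
    flows = if (config$keep_flows) flows else NULL,
    descriptors = descriptors, registered_magnitude = reg_mag,
    body_mask = body, log = logdf, config = config
  ), class = "workflow_result")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat(sprintf(
    "workflow_result (%s): reference frame %d, max dT = %.1f degC, lesion = %.2f cm^3\n",
    x$config$method, x$reference_frame,
    max(x$temperature$delta_t, na.rm = TRUE),
    lesion_volume(x$dose, x$config$dose_threshold)))
  invisible(x)
}

#' Run and compare several workflows
#'
#' Runs each configuration on the same series and evaluates temperature
#' error, endpoint error, lesion volumes (with Bland-Altman agreement
#' against the designated reference) and time-to-threshold maps. The
#' reference is the synthetic ground truth when supplied, otherwise the
#' first workflow's output (gold standard on motion-free series).
#'
#' @param series A [dynamic_series()].
#' @param configs Named list of [workflow_config()]s (>= 2).
#' @param truth Optional `ground_truth` from [generate_series()].
#' @param roi Optional [make_roi()]; built from the reference temperature
#'   around the hotspot centre when `truth` is given.
#' @param eval_frames Frame window for temperature metrics (default: first
#'   100 frames after heating onset when `truth` is given, else the
#'   intervention frames).
#' @return List of class `workflow_comparison` with per-workflow `results`,
#'   `temperature_rmse`, `aee`, `volumes`, `bland_altman` and
#'   `time_to_threshold` difference maps.
#' @export
compare_workflows <- function(series, configs, truth = NULL, roi = NULL,
                              eval_frames = NULL) {
  if (length(configs) < 2) stop("need at least 2 workflows", call. = FALSE)
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, function(cf) cf$method, "")
  }
  results <- lapply(configs, function(cf) run_workflow(series, cf))
  nt <- n_frames(series)

  # reference temperature + ROI; with ground truth, each workflow is
  # evaluated against the truth warped to ITS OWN reference position so
  # the comparison is voxel-aligned
  if (!is.null(truth)) {
    center <- truth$config$hotspot_center
    heat_start <- truth$config$heating_window[1]
    ref_temps <- lapply(results, function(res)
      true_temperature_at_reference(truth, res$reference_frame))
  } else {
    center <- round(dim(results[[1]]$temperature$delta_t)[1:3] / 2)
    heat_start <- configs[[1]]$learning_frames + 1L
    ref_temps <- lapply(results, function(res)
      results[[1]]$temperature$delta_t)
  }
  rois <- lapply(ref_temps, function(tt)
    if (is.null(roi)) make_roi(tt, center) else roi)
  roi <- rois[[1]]
  if (is.null(eval_frames)) {
    eval_frames <- heat_start:min(heat_start + 99L, nt)
  }

  temp_rmse <- lapply(seq_along(results), function(i)
    temperature_error(results[[i]]$temperature$delta_t, ref_temps[[i]],
                      rois[[i]], eval_frames))
  names(temp_rmse) <- names(results)

  # endpoint error vs true motion at the evaluation frames (when available)
  aee <- NULL
  if (!is.null(truth)) {
    aee <- lapply(seq_along(results), function(i) {
      res <- results[[i]]
      if (is.null(res$flows)) return(NA_real_)
      vals <- vapply(eval_frames, function(t) {
        tf <- true_flow_to_reference(truth, t, res$reference_frame)
        endpoint_error(res$flows[[t]], tf, rois[[i]],
                       series$voxel_spacing[1:2])$aee
      }, 0)
      mean(vals)
    })
    names(aee) <- names(results)
  }

  # lesion volumes over the last 10 frames + agreement vs the reference
  vol_frames <- max(1L, nt - 9L):nt
  volumes <- lapply(results, function(res)
    lesion_volume_series(res$dose, res$config$dose_threshold,
                         series$voxel_spacing, vol_frames))
  ref_vol <- if (!is.null(truth)) {
    true_dose <- accumulate_cem43(truth$delta_t, 37, series$frame_interval)
    lesion_volume_series(true_dose, 240, series$voxel_spacing, vol_frames)
  } else {
    volumes[[1]]
  }
  ba <- lapply(volumes, function(v) bland_altman(v, ref_vol))

  ttt <- lapply(results, function(res)
    time_to_threshold(res$dose, res$config$dose_threshold))
  ttt_diff <- lapply(ttt[-1], function(m) time_to_threshold_diff(m, ttt[[1]]))

  structure(list(results = results, roi = roi, eval_frames = eval_frames,
                 temperature_rmse = temp_rmse, aee = aee,
                 volumes = volumes, reference_volumes = ref_vol,
                 bland_altman = ba, time_to_threshold = ttt,
                 time_to_threshold_diff = ttt_diff),
            class = "workflow_comparison")
}

#' @export
print.workflow_comparison <- function(x, ...) {
  cat("workflow_comparison\n")
  for (nm in names(x$results)) {
    cat(sprintf(
      "  %-16s median T-RMSE = %5.2f degC | final lesion = %.2f cm^3 | volume bias = %+.2f cm^3\n",
      nm, x$temperature_rmse[[nm]]$summary["median"],
      utils::tail(x$volumes[[nm]], 1), x$bland_altman[[nm]]$bias))
  }
  invisible(x)
}
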