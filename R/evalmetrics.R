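# Evaluation metrics: image intercorrelation, (N)RMSE, endpoint error of
# flow fields, per-frame temperature error over the ablation ROI, and
# Bland-Altman agreement of lesion volumes.

#' Intercorrelation coefficient between two stacks
#'
#' Pearson correlation between the current and reference magnitude images,
#' computed over the whole image slice by slice and averaged over slices.
#' Invariant under positive affine intensity maps; bounded in `[-1, 1]`.
#'
#' @param current,reference Stacks of identical shape.
#' @return Scalar in `[-1, 1]`, or `NA` (with a warning) if either image
#'   has zero variance.
#' @export
intercorrelation <- function(current, reference) {
  current <- as_3d(current); reference <- as_3d(reference)
  stopifnot_same_dim(current, reference, "current and reference")
  vals <- vapply(seq_len(dim(current)[3]), function(s) {
    a <- as.vector(current[, , s]); b <- as.vector(reference[, , s])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
  if (anyNA(vals)) {
    warning("zero-variance slice: intercorrelation undefined")
  }
  mean(vals)
}

#' Root mean square error between two stacks
#'
#' `sqrt(sum((I - J)^2) / N)` over the (optionally masked) voxels. Despite
#' the conventional name "NRMSE" this quantity carries the units of the
#' input (intensities, or degrees C for temperature stacks); set
#' `normalize = TRUE` to divide by the reference intensity range.
#'
#' @param current,reference Stacks of identical shape.
#' @param mask Optional logical mask of voxels to include.
#' @param normalize Divide by `diff(range(reference))` (default `FALSE`).
#' @return Scalar error.
#' @export
nrmse <- function(current, reference, mask = NULL, normalize = FALSE) {
  stopifnot_same_dim(current, reference, "current and reference")
  diff2 <- (current - reference)^2
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty mask", call. = FALSE)
    diff2 <- diff2[mask]
  }
  out <- sqrt(mean(diff2, na.rm = TRUE))
  if (normalize) out <- out / diff(range(reference, na.rm = TRUE))
  out
}

#' Define the ablation evaluation ROI
#'
#' A `size x size` in-plane box centred on the ablated area over the given
#' slices, restricted to voxels whose temperature change exceeded
#' `threshold` degrees C at any frame (the signal-loss artifact is very
#' localized, so only substantially heated voxels are informative).
#'
#' @param temperature A [temperature_series()] or 4D temperature array used
#'   to build the inclusion mask (typically the ground truth or gold
#'   standard).
#' @param center Voxel coords `(row, col, slice)` of the ablation centre
#'   (supplied explicitly; needle detection is out of scope).
#' @param size In-plane box side in voxels (default 19).
#' @param slices Slice indices covered (default: all slices).
#' @param threshold Inclusion threshold in degrees C (default 10).
#' @return Object of class `roi_spec` with `rows`, `cols`, `slices`,
#'   `center`, `size` and the logical 3D `inclusion_mask`.
#' @export
make_roi <- function(temperature, center, size = 19L, slices = NULL,
                     threshold = 10) {
  dT <- if (inherits(temperature, "temperature_series")) {
    temperature$delta_t
  } else {
    as_4d(temperature)
  }
  d <- dim(dT)
  half <- (size - 1) %/% 2
  rows <- max(1, center[1] - half):min(d[1], center[1] + half)
  cols <- max(1, center[2] - half):min(d[2], center[2] + half)
  if (is.null(slices)) slices <- seq_len(d[3])
  tmax <- apply(dT, 1:3, function(v) {
    if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)
  })
  inc <- array(FALSE, d[1:3])
  inc[rows, cols, slices] <- tmax[rows, cols, slices] > threshold
  structure(list(rows = rows, cols = cols, slices = slices,
                 center = center, size = size,
                 inclusion_mask = inc), class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("roi_spec: %dx%d box at (%s), %d slice(s), %d included voxel(s)\n",
              length(x$rows), length(x$cols),
              paste(x$center, collapse = ", "), length(x$slices),
              sum(x$inclusion_mask)))
  invisible(x)
}

#' Endpoint error between two flow fields
#'
#' Per-voxel Euclidean distance between the estimated and reference
#' displacement vectors, converted to millimetres with the in-plane voxel
#' spacing, and its average (AEE) over the ROI inclusion mask (all included
#' voxels pooled across slices).
#'
#' @param flow,ref_flow [flow_field()]s on the same grid (`ref_flow` is the
#'   reference/ground-truth motion).
#' @param roi Optional [make_roi()] result; without it the AEE averages over
#'   all finite voxels.
#' @param voxel_spacing In-plane voxel size in mm (row, col); a scalar is
#'   recycled.
#' @return List with `ee` (3D map, mm) and `aee` (scalar, mm).
#' @export
endpoint_error <- function(flow, ref_flow, roi = NULL,
                           voxel_spacing = c(1, 1)) {
  stopifnot_same_dim(flow$u, ref_flow$u, "flow fields")
  if (length(voxel_spacing) == 1) voxel_spacing <- rep(voxel_spacing, 2)
  du_mm <- (flow$u - ref_flow$u) * voxel_spacing[2]  # u = column shift
  dv_mm <- (flow$v - ref_flow$v) * voxel_spacing[1]  # v = row shift
  ee <- sqrt(du_mm^2 + dv_mm^2)
  if (is.null(roi)) {
    aee <- mean(ee, na.rm = TRUE)
  } else {
    if (!any(roi$inclusion_mask)) stop("empty inclusion mask", call. = FALSE)
    aee <- mean(ee[roi$inclusion_mask], na.rm = TRUE)
  }
  list(ee = ee, aee = aee)
}

#' Per-frame temperature error over the ablation ROI
#'
#' Root mean square temperature difference between a test and a reference
#' temperature series over the ROI inclusion mask, one value per evaluated
#' frame, with a whisker-style distribution summary. By default the
#' evaluation window is the first 100 frames after heating onset (truncated
#' to availability).
#'
#' @param test,reference [temperature_series()] or 4D arrays on the same
#'   grid and frames.
#' @param roi A [make_roi()] result.
#' @param frames Integer frame window to evaluate.
#' @return List with `frames`, `rmse` (degrees C per frame) and `summary`
#'   (median, quartiles, extremes).
#' @export
temperature_error <- function(test, reference, roi, frames = NULL) {
  a <- if (inherits(test, "temperature_series")) test$delta_t else as_4d(test)
  b <- if (inherits(reference, "temperature_series")) reference$delta_t else
    as_4d(reference)
  stopifnot_same_dim(a, b, "temperature stacks")
  nt <- dim(a)[4]
  if (is.null(frames)) frames <- seq_len(nt)
  if (any(frames < 1 | frames > nt)) {
    stop(sprintf("frame window outside series (1..%d)", nt), call. = FALSE)
  }
  if (!any(roi$inclusion_mask)) stop("empty inclusion mask", call. = FALSE)
  rmse <- vapply(frames, function(t) {
    nrmse(a[, , , t][roi$inclusion_mask], b[, , , t][roi$inclusion_mask])
  }, 0)
  qs <- stats::quantile(rmse, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
  list(frames = frames, rmse = rmse,
       summary = c(min = unname(qs[1]), q1 = unname(qs[2]),
                   median = unname(qs[3]), q3 = unname(qs[4]),
                   max = unname(qs[5])))
}

#' Bland-Altman agreement of paired measurements
#'
#' `bias = mean(a - b)`; limits of agreement `bias +/- 1.96 sd(a - b)`.
#'
#' @param volumes_a,volumes_b Paired measurements (e.g. lesion volumes in
#'   cm^3), at least 2 pairs.
#' @return List with `bias`, `sd`, `lower`, `upper` and the paired
#'   differences.
#' @export
bland_altman <- function(volumes_a, volumes_b) {
  if (length(volumes_a) != length(volumes_b)) {
    stop("paired measurements must have equal length", call. = FALSE)
  }
  if (length(volumes_a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- volumes_a - volumes_b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       differences = d, means = (volumes_a + volumes_b) / 2)
}
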