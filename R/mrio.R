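# Reading/writing dynamic magnitude+phase MR series and result maps.
#
# Conventions (fixed package-wide):
#   * arrays are [row, col, slice, frame]; coordinates are 1-based (R);
#   * displacement u = column shift, v = row shift, in voxels;
#   * phase is stored in radians on [-pi, pi);
#   * voxel_spacing = (row mm, col mm, slice mm).

#' Construct a dynamic magnitude/phase series
#'
#' Bundles a time-ordered multi-slice MR acquisition: per-frame magnitude and
#' phase stacks plus timing and voxel geometry. This is the common input
#' container for registration, thermometry and dosimetry.
#'
#' @param magnitude 4D numeric array `[row, col, slice, frame]`, values >= 0
#'   (arbitrary units).
#' @param phase 4D numeric array of the same shape, radians. Values are
#'   wrapped into \eqn{[-\pi, \pi)} via [normalize_phase()].
#' @param timestamps Numeric vector, one acquisition time (seconds) per frame,
#'   strictly increasing.
#' @param voxel_spacing Numeric length-3, voxel size in mm
#'   (row, col, slice).
#' @param frame_interval Nominal seconds between frames; defaults to the
#'   median timestamp difference.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(magnitude, phase, timestamps,
                           voxel_spacing = c(2.5, 2.5, 3),
                           frame_interval = NULL) {
  magnitude <- as_4d(magnitude)
  phase <- as_4d(phase)
  if (!identical(dim(magnitude), dim(phase))) {
    dm <- dim(magnitude)[4]; dp <- dim(phase)[4]
    if (dm != dp) {
      stop(sprintf(
        "magnitude has %d frame(s) but phase has %d: %d unpaired frame(s)",
        dm, dp, abs(dm - dp)), call. = FALSE)
    }
    stop("magnitude and phase grids differ", call. = FALSE)
  }
  if (any(magnitude < 0, na.rm = TRUE)) {
    stop("magnitude values must be >= 0", call. = FALSE)
  }
  nt <- dim(magnitude)[4]
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != nt) {
    stop(sprintf("need %d timestamps, got %d", nt, length(timestamps)),
         call. = FALSE)
  }
  if (nt > 1 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (is.null(frame_interval)) {
    frame_interval <- if (nt > 1) stats::median(diff(timestamps)) else 1
  }
  structure(list(
    magnitude = magnitude,
    phase = normalize_phase(phase),
    timestamps = timestamps,
    voxel_spacing = as.numeric(voxel_spacing),
    frame_interval = frame_interval
  ), class = "dynamic_series")
}

as_4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array", call. = FALSE)
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 4) stop("expected a 2D/3D/4D array", call. = FALSE)
  x
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf(
    "dynamic_series: %d x %d x %d voxels, %d frames, dt = %.3g s, spacing = %s mm\n",
    d[1], d[2], d[3], d[4], x$frame_interval,
    paste(signif(x$voxel_spacing, 3), collapse = " x ")))
  invisible(x)
}

n_frames <- function(series) dim(series$magnitude)[4]

# extract one frame's 3D stack (dimensions preserved for single slices)
frame_stack <- function(arr4d, t) {
  d <- dim(arr4d)
  array(arr4d[, , , t], d[1:3])
}

#' Rescale stored integer phase to radians
#'
#' Scanner exports commonly store phase as integers. The default dialect maps
#' stored values \eqn{p \in [0, 4096)} linearly onto \eqn{[-\pi, \pi)} as
#' \eqn{(p/4096)\,2\pi - \pi}; pass `slope`/`intercept` to override for other
#' vendors.
#'
#' @param p Numeric array of stored phase values.
#' @param slope,intercept Linear map `radians = slope * p + intercept`.
#' @return Phase in radians, wrapped to \eqn{[-\pi, \pi)}.
#' @export
#' @examples
#' rescale_phase(c(0, 2048, 4095))
rescale_phase <- function(p, slope = 2 * pi / 4096, intercept = -pi) {
  wrap_phase(slope * p + intercept)
}

#' Normalize phase values to radians in \eqn{[-\pi, \pi)}
#'
#' Values already inside \eqn{[-\pi, \pi)} are returned unchanged (the
#' operation is idempotent). Arrays whose range clearly indicates integer
#' storage (all values in `[0, 4096)` with span greater than `2*pi`) are run
#' through [rescale_phase()]; any other out-of-range values are wrapped.
#'
#' @param phase Numeric array.
#' @param rescale Optional list with `slope` and `intercept` overriding the
#'   stored-integer dialect.
#' @return Phase in radians in \eqn{[-\pi, \pi)}.
#' @export
normalize_phase <- function(phase, rescale = NULL) {
  rng <- range(phase, na.rm = TRUE)
  if (!is.null(rescale)) {
    return(rescale_phase(phase, rescale$slope, rescale$intercept))
  }
  if (rng[1] >= -pi && rng[2] < pi) return(phase)
  if (rng[1] >= 0 && rng[2] < 4096 && diff(rng) > 2 * pi) {
    return(rescale_phase(phase))
  }
  wrap_phase(phase)
}

#' Read a dynamic series from disk
#'
#' Reads a paired magnitude/phase NIfTI export: either a directory containing
#' `magnitude.nii[.gz]` and `phase.nii[.gz]` (plus optional `timestamps.csv`
#' with columns `frame,time_s`), or a character vector of the two file paths
#' `(magnitude, phase)`. 4D volumes are interpreted with time last.
#'
#' @param path Directory or length-2 character vector (magnitude, phase).
#' @param format `"nifti"`. (`"dicom"` is recognised but not supported in
#'   this build; convert DICOM series to NIfTI first, e.g. with dcm2niix.)
#' @param phase_rescale Optional `list(slope=, intercept=)` stored-phase
#'   dialect override, see [normalize_phase()].
#' @return A [dynamic_series()].
#' @export
read_series <- function(path, format = c("nifti", "dicom"),
                        phase_rescale = NULL) {
  format <- match.arg(format)
  if (format == "dicom") {
    stop(paste("DICOM ingestion is not available in this build;",
               "convert the series to NIfTI (e.g. dcm2niix) and use",
               'format = "nifti"'), call. = FALSE)
  }
  if (length(path) == 1 && dir.exists(path)) {
    magf <- first_existing(file.path(path, c("magnitude.nii", "magnitude.nii.gz")))
    phaf <- first_existing(file.path(path, c("phase.nii", "phase.nii.gz")))
    tsf <- file.path(path, "timestamps.csv")
  } else if (length(path) == 2) {
    magf <- path[1]; phaf <- path[2]; tsf <- NA_character_
  } else {
    stop("path must be a directory or c(magnitude_file, phase_file)",
         call. = FALSE)
  }
  mag <- RNifti::readNifti(magf)
  pha <- RNifti::readNifti(phaf)
  pd <- RNifti::pixdim(mag)
  magarr <- as_4d(strip_attrs(mag))
  phaarr <- as_4d(strip_attrs(pha))
  if (dim(magarr)[4] != dim(phaarr)[4]) {
    stop(sprintf(
      "magnitude has %d frame(s) but phase has %d: %d unpaired frame(s)",
      dim(magarr)[4], dim(phaarr)[4], abs(dim(magarr)[4] - dim(phaarr)[4])),
      call. = FALSE)
  }
  nt <- dim(magarr)[4]
  dt <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  ts <- (seq_len(nt) - 1) * dt
  if (!is.na(tsf) && file.exists(tsf)) {
    tab <- utils::read.csv(tsf)
    ts <- as.numeric(tab$time_s)
  }
  dynamic_series(magarr, normalize_phase(phaarr, phase_rescale), ts,
                 voxel_spacing = pd[1:3], frame_interval = dt)
}

# plain numeric array, shedding NIfTI pointers and header attributes
strip_attrs <- function(x) {
  array(as.vector(x), dim = dim(x))
}

first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (length(hit) == 0) {
    stop(sprintf("none of %s found", paste(paths, collapse = ", ")),
         call. = FALSE)
  }
  hit[1]
}

#' Write a dynamic series to NIfTI
#'
#' Writes `magnitude.nii`, `phase.nii` and `timestamps.csv` into `path`
#' (created if needed). Voxel spacing and frame interval go into the NIfTI
#' pixdim so that [read_series()] round-trips the geometry. Files are written
#' uncompressed so identical inputs give bit-identical outputs.
#'
#' @param series A [dynamic_series()].
#' @param path Output directory.
#' @return Invisibly, the paths written.
#' @export
write_series <- function(series, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", path),
                  call. = FALSE)
  }
  magf <- file.path(path, "magnitude.nii")
  phaf <- file.path(path, "phase.nii")
  write_map(series$magnitude, magf, voxel_spacing = series$voxel_spacing,
            frame_interval = series$frame_interval)
  write_map(series$phase, phaf, voxel_spacing = series$voxel_spacing,
            frame_interval = series$frame_interval)
  tsf <- file.path(path, "timestamps.csv")
  utils::write.csv(
    data.frame(frame = seq_along(series$timestamps),
               time_s = series$timestamps),
    tsf, row.names = FALSE)
  invisible(c(magnitude = magf, phase = phaf, timestamps = tsf))
}

#' Write a single map or stack to NIfTI
#'
#' Writes any scalar quantity on the image grid (temperature, dose,
#' endpoint-error maps, ...) as an uncompressed NIfTI-1 file. `NA` values are
#' stored as NaN and survive the round trip.
#'
#' @param stack 2D/3D/4D numeric array.
#' @param path Output file (use a `.nii` extension).
#' @param voxel_spacing Length-3 voxel size in mm.
#' @param frame_interval Seconds between frames for 4D stacks.
#' @return Invisibly, `path`.
#' @export
write_map <- function(stack, path, voxel_spacing = c(1, 1, 1),
                      frame_interval = 1) {
  arr <- as_4d(stack)
  img <- structure(arr, pixdim = c(voxel_spacing, frame_interval))
  ok <- tryCatch({
    RNifti::writeNifti(img, path, datatype = "double")
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

#' Read a map written by [write_map()]
#'
#' @param path NIfTI file.
#' @return Numeric array (singleton trailing dimensions dropped).
#' @export
read_map <- function(path) {
  arr <- strip_attrs(RNifti::readNifti(path))
  d <- dim(arr)
  while (length(d) > 2 && d[length(d)] == 1L) {
    d <- d[-length(d)]
  }
  dim(arr) <- d
  arr
}
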