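# Respiration-induced susceptibility phase correction: the background phase
# at any breathing state is modelled per voxel as a first-order (linear)
# function of a small set of motion descriptors, learned by ordinary least
# squares over the heating-free preparative frames and frozen thereafter.

#' Fit the motion-parameterized background-phase model
#'
#' Per-voxel ordinary least squares of the (registered, temporally
#' unwrapped) phase against `[1, descriptors]`: the intercept becomes the
#' baseline phase, the slopes become one coefficient map per descriptor.
#' With descriptors taken as the PCA motion-basis coefficients, the same
#' model form serves both the conventional and the PCA-constrained
#' registration workflows.
#'
#' @param registered_phases Learning-frame phases registered to the
#'   reference position and temporally unwrapped: a list of 3D stacks or a
#'   4D array `[row, col, slice, frame]`, radians.
#' @param descriptors One motion-descriptor vector per learning frame: a
#'   list or an `n_frames x k` matrix.
#' @return Object of class `susceptibility_model` with `baseline_phase`
#'   (3D), `coefficient_maps` (list of k 3D arrays, radians per descriptor
#'   unit) and `descriptor_count`.
#' @export
fit_susceptibility_model <- function(registered_phases, descriptors) {
  if (is.list(registered_phases)) {
    phases <- array(unlist(registered_phases),
                    c(dim(as_3d(registered_phases[[1]])),
                      length(registered_phases)))
  } else {
    phases <- as_4d(registered_phases)
  }
  d <- dim(phases)
  nt <- d[4]
  if (is.list(descriptors)) {
    descriptors <- do.call(rbind, lapply(descriptors, as.numeric))
  }
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) != nt) {
    stop(sprintf("need one descriptor vector per frame (%d), got %d",
                 nt, nrow(descriptors)), call. = FALSE)
  }
  k <- ncol(descriptors)
  if (nt < k + 1) {
    stop(sprintf(
      "underdetermined fit: %d learning frames for %d descriptor(s) + intercept",
      nt, k), call. = FALSE)
  }
  D <- cbind(1, descriptors)
  P <- t(matrix(phases, ncol = nt))          # nt x nvox
  P[!is.finite(P)] <- 0
  coef <- tryCatch(
    solve(crossprod(D), crossprod(D, P)),
    error = function(e) {
      # rank-deficient descriptors (e.g. constant): least-squares pseudo-solve
      qr.coef(qr(D), P)
    })
  coef[!is.finite(coef)] <- 0
  baseline <- array(coef[1, ], d[1:3])
  maps <- lapply(seq_len(k), function(j) array(coef[j + 1, ], d[1:3]))
  structure(list(baseline_phase = baseline, coefficient_maps = maps,
                 descriptor_count = k), class = "susceptibility_model")
}

#' @export
print.susceptibility_model <- function(x, ...) {
  cat(sprintf(
    "susceptibility_model: %d descriptor map(s) on a %s grid\n",
    x$descriptor_count, paste(dim(x$baseline_phase), collapse = "x")))
  invisible(x)
}

#' Predict the background phase for a motion state
#'
#' \eqn{\phi_{ref} = \phi_0 + \sum_k c_k B_k} where `c` is the current
#' motion-descriptor vector and `B_k` the learned coefficient maps.
#'
#' @param model A [fit_susceptibility_model()] result.
#' @param descriptors Numeric vector of length `descriptor_count`.
#' @return 3D phase stack, radians (not wrapped: the model lives in the
#'   unwrapped phase domain).
#' @export
predict_background_phase <- function(model, descriptors) {
  descriptors <- as.numeric(descriptors)
  if (length(descriptors) != model$descriptor_count) {
    stop(sprintf("expected %d descriptor(s), got %d",
                 model$descriptor_count, length(descriptors)),
         call. = FALSE)
  }
  out <- model$baseline_phase
  for (k in seq_along(descriptors)) {
    out <- out + descriptors[k] * model$coefficient_maps[[k]]
  }
  out
}
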