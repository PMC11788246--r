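# Deformable registration of dynamic series: conventional Horn-Schunck
# optical flow, and optical flow constrained to a PCA subspace of breathing
# motion learned during a preparative phase. All flows are slice-wise 2D
# (the acquisition is a stack of thin slices; through-plane motion is out of
# scope) and use the pull-back convention:
#   warped(x) = moving(x + flow(x)),  flow = (u, v) in voxels,
# so a flow field estimated against a reference frame lives on the reference
# grid.

#' Construct a flow field
#'
#' @param u,v 3D numeric arrays `[row, col, slice]` of column (`u`) and row
#'   (`v`) displacements in voxels.
#' @return Object of class `flow_field`.
#' @export
flow_field <- function(u, v) {
  u <- as_3d(u); v <- as_3d(v)
  stopifnot_same_dim(u, v, "u and v")
  structure(list(u = u, v = v), class = "flow_field")
}

as_3d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array", call. = FALSE)
  if (length(d) == 2) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 3) stop("expected a 2D or 3D array", call. = FALSE)
  x
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("flow_field: %s voxels, mean |f| = %.3g, max |f| = %.3g voxels\n",
              paste(dim(x$u), collapse = "x"),
              mean(mag, na.rm = TRUE), max(mag, na.rm = TRUE)))
  invisible(x)
}

flat_flow <- function(flow) c(as.vector(flow$u), as.vector(flow$v))

unflat_flow <- function(vec, dims) {
  n <- prod(dims)
  flow_field(array(vec[seq_len(n)], dims), array(vec[n + seq_len(n)], dims))
}

#' Default Horn-Schunck parameters
#'
#' Regularization weight `alpha` applies to unit-normalized intensities;
#' `n_iterations` Jacobi sweeps are run per warp update, with
#' `pyramid_levels` coarse-to-fine levels (downscale x2) and convergence
#' declared when the mean flow update falls below `tolerance` voxels.
#'
#' @param alpha Smoothness weight (default 0.1).
#' @param n_iterations Jacobi iterations per warp update (default 100).
#' @param pyramid_levels Number of pyramid levels (default 3).
#' @param n_warps Warp updates per level (default 3).
#' @param tolerance Convergence tolerance in voxels (default 1e-3).
#' @return A list of parameters.
#' @export
hs_params <- function(alpha = 0.1, n_iterations = 100L, pyramid_levels = 3L,
                      n_warps = 3L, tolerance = 1e-3) {
  list(alpha = alpha, n_iterations = as.integer(n_iterations),
       pyramid_levels = as.integer(pyramid_levels),
       n_warps = as.integer(n_warps), tolerance = tolerance)
}

# normalize a stack pair onto a shared unit scale for the data term
normalize_pair <- function(moving, reference) {
  sc <- max(abs(reference), na.rm = TRUE)
  if (!is.finite(sc) || sc == 0) sc <- 1
  list(moving = moving / sc, reference = reference / sc, scale = sc)
}

#' Estimate deformable motion by Horn-Schunck optical flow
#'
#' Slice-by-slice 2D Horn-Schunck solution minimising the brightness
#' constancy data term plus `alpha^2` times the smoothness term, solved
#' coarse-to-fine with intermediate warping. The returned flow maps the
#' reference grid into the moving frame (`moving(x + flow(x)) ~ reference(x)`).
#'
#' @param moving,reference 2D/3D magnitude stacks of identical shape.
#' @param params See [hs_params()].
#' @return A [flow_field()].
#' @export
estimate_flow_hs <- function(moving, reference, params = hs_params()) {
  moving <- as_3d(moving); reference <- as_3d(reference)
  stopifnot_same_dim(moving, reference, "moving and reference")
  if (any(!is.finite(moving)) || any(!is.finite(reference))) {
    stop("non-finite values in input images", call. = FALSE)
  }
  bump_counter("hs")
  nrm <- normalize_pair(moving, reference)
  dims <- dim(moving)
  u <- array(0, dims); v <- array(0, dims)
  if (stats::var(as.vector(reference)) == 0 ||
      stats::var(as.vector(moving)) == 0) {
    warning("zero-variance image: returning zero flow")
    return(flow_field(u, v))
  }
  for (s in seq_len(dims[3])) {
    fl <- hs_slice(nrm$moving[, , s], nrm$reference[, , s], params)
    u[, , s] <- fl$u; v[, , s] <- fl$v
  }
  flow_field(u, v)
}

hs_slice <- function(mov, ref, params) {
  nr <- nrow(mov); nc <- ncol(mov)
  # cap levels so the coarsest image keeps >= 16 px per side
  maxlev <- max(1L, floor(log2(min(nr, nc) / 16)) + 1L)
  nlev <- min(params$pyramid_levels, maxlev)
  sizes <- lapply(rev(seq_len(nlev) - 1L),
                  function(l) c(max(8L, round(nr / 2^l)),
                                max(8L, round(nc / 2^l))))
  u <- matrix(0, sizes[[1]][1], sizes[[1]][2])
  v <- matrix(0, sizes[[1]][1], sizes[[1]][2])
  for (li in seq_along(sizes)) {
    sz <- sizes[[li]]
    # anti-alias prefilter proportional to the decimation factor
    dec <- nr / sz[1]
    movl <- resize_bilinear(if (dec > 1) gauss_smooth(mov, 0.5 * dec) else mov,
                            sz[1], sz[2])
    refl <- resize_bilinear(if (dec > 1) gauss_smooth(ref, 0.5 * dec) else ref,
                            sz[1], sz[2])
    if (li > 1) {
      prev <- sizes[[li - 1]]
      u <- resize_bilinear(u, sz[1], sz[2]) * (sz[2] / prev[2])
      v <- resize_bilinear(v, sz[1], sz[2]) * (sz[1] / prev[1])
    }
    for (w in seq_len(params$n_warps)) {
      u0 <- u; v0 <- v
      wm <- warp_slice(movl, u0, v0)
      nas <- is.na(wm)
      if (any(nas)) wm[nas] <- refl[nas]
      avg <- (wm + refl) / 2
      g <- image_gradient(avg)
      Ix <- g$gx; Iy <- g$gy
      # linearize about (u0, v0) and solve for the TOTAL flow, so the
      # smoothness term regularizes the full field
      It <- wm - refl - Ix * u0 - Iy * v0
      denom <- params$alpha^2 + Ix^2 + Iy^2
      for (it in seq_len(params$n_iterations)) {
        ubar <- hs_local_average(u); vbar <- hs_local_average(v)
        tfac <- (Ix * ubar + Iy * vbar + It) / denom
        u_new <- ubar - Ix * tfac
        v_new <- vbar - Iy * tfac
        delta <- mean(abs(u_new - u) + abs(v_new - v))
        u <- u_new; v <- v_new
        if (delta < params$tolerance) break
      }
    }
  }
  list(u = u, v = v)
}

#' Warp an image stack by a flow field
#'
#' Pull-back bilinear warp: `out(x) = image(x + flow(x))`. Complex images are
#' warped by interpolating real and imaginary parts separately (use this for
#' phase: warp `magnitude * exp(1i * phase)` and retake `Arg`), which avoids
#' interpolating across phase wraps. Samples falling outside the grid are
#' marked `NA` rather than extrapolated.
#'
#' @param image 2D/3D numeric or complex stack.
#' @param flow A [flow_field()] on the same grid.
#' @param interpolation Only `"bilinear"` is implemented.
#' @return Warped stack of the same shape, `NA` where out of bounds.
#' @export
warp_image <- function(image, flow, interpolation = "bilinear") {
  interpolation <- match.arg(interpolation, "bilinear")
  cplx <- is.complex(image)
  image <- as_3d(image)
  stopifnot_same_dim(if (cplx) Re(image) else image, flow$u,
                     "image and flow")
  out <- image
  for (s in seq_len(dim(image)[3])) {
    u <- flow$u[, , s]; v <- flow$v[, , s]
    if (cplx) {
      re <- warp_slice(Re(image[, , s]), u, v)
      im <- warp_slice(Im(image[, , s]), u, v)
      out[, , s] <- complex(real = re, imaginary = im)
    } else {
      out[, , s] <- warp_slice(image[, , s], u, v)
    }
  }
  out
}

#' Select the reference frame from the initial stacks
#'
#' Estimates the displacement of each of the first `n_initial` frames against
#' frame 1 by Horn-Schunck flow, reduces each to a scalar position (spatial
#' mean of the flow component along the dominant motion axis), and returns
#' the frame sitting at the (lower) median position. For a gated series all
#' positions are nearly equal and the earliest tied frame is returned; for a
#' fixed-frequency series this lands mid breathing cycle, minimising the
#' displacements later estimated against it.
#'
#' @param series A [dynamic_series()].
#' @param n_initial Number of initial frames to consider (default 10).
#' @param params Flow parameters, see [hs_params()].
#' @return Integer frame index (1-based).
#' @export
select_reference_frame <- function(series, n_initial = 10L,
                                   params = hs_params()) {
  n_initial <- as.integer(n_initial)
  if (n_initial < 3) stop("n_initial must be >= 3", call. = FALSE)
  if (n_frames(series) < n_initial) {
    stop(sprintf("series has %d frames, need >= %d", n_frames(series),
                 n_initial), call. = FALSE)
  }
  ref0 <- frame_stack(series$magnitude, 1)
  flows <- vector("list", n_initial)
  flows[[1]] <- flow_field(array(0, dim(as_3d(ref0))),
                           array(0, dim(as_3d(ref0))))
  for (t in 2:n_initial) {
    flows[[t]] <- estimate_flow_hs(frame_stack(series$magnitude, t), ref0,
                                   params)
  }
  mu <- vapply(flows, function(f) mean(abs(f$u)), 0)
  mv <- vapply(flows, function(f) mean(abs(f$v)), 0)
  dominant <- if (mean(mv) >= mean(mu)) "v" else "u"
  pos <- vapply(flows, function(f) mean(f[[dominant]]), 0)
  ord <- order(pos)
  lower_median <- ord[ceiling(n_initial / 2)]
  # tie rule: earliest frame whose position equals the median position
  which(pos == pos[lower_median])[1]
}

#' Build a PCA basis of breathing motion
#'
#' Principal component analysis of mean-removed, flattened `(u, v)` fields
#' collected during the preparative (heating-free) phase. All slices are
#' concatenated so one coefficient vector describes the whole stack. The
#' smallest number of components reaching `variance_threshold` of the total
#' variance is retained, capped at `max_components`.
#'
#' @param flows List of [flow_field()]s (>= 2, same grid).
#' @param variance_threshold Fraction of variance to capture (default 0.95).
#' @param max_components Cap on retained components (default 5).
#' @return Object of class `flow_basis` with `mean_flow`, `components`
#'   (orthonormal [flow_field()]s), `explained_variance` and `n_retained`.
#' @export
build_flow_basis <- function(flows, variance_threshold = 0.95,
                             max_components = 5L) {
  if (length(flows) < 2) stop("need at least 2 flows", call. = FALSE)
  dims <- dim(flows[[1]]$u)
  X <- t(vapply(flows, flat_flow, numeric(2 * prod(dims))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total_var <- sum(Xc^2)
  mean_flow <- unflat_flow(mu, dims)
  if (total_var < 1e-24 * max(1, sum(mu^2))) {
    warning("all flows identical: basis has zero components")
    return(structure(list(mean_flow = mean_flow, components = list(),
                          explained_variance = numeric(0), n_retained = 0L,
                          dims = dims), class = "flow_basis"))
  }
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / sum(sv$d^2)
  nonzero <- sv$d^2 > 1e-12 * sum(sv$d^2)
  k_needed <- which(cumsum(ev) >= variance_threshold)[1]
  k <- min(k_needed, max_components, sum(nonzero))
  comps <- lapply(seq_len(k), function(j) unflat_flow(sv$v[, j], dims))
  # per-component score spread over the learning set: the statistical range
  # of breathing motion, used to bound coefficients during intervention
  score_sd <- sv$d[seq_len(k)] / sqrt(max(1, length(flows) - 1))
  structure(list(mean_flow = mean_flow, components = comps,
                 explained_variance = ev[seq_len(k)],
                 score_sd = score_sd,
                 n_retained = as.integer(k), dims = dims),
            class = "flow_basis")
}

#' @export
print.flow_basis <- function(x, ...) {
  cat(sprintf("flow_basis: %d component(s) on a %s grid, explained variance %s\n",
              x$n_retained, paste(x$dims, collapse = "x"),
              paste(signif(x$explained_variance, 3), collapse = ", ")))
  invisible(x)
}

#' Reconstruct a flow from basis coefficients
#'
#' `flow = mean_flow + sum_k a_k * component_k`.
#'
#' @param basis A [build_flow_basis()] result.
#' @param coefficients Numeric vector of length `n_retained`.
#' @return A [flow_field()].
#' @export
basis_flow <- function(basis, coefficients) {
  vec <- flat_flow(basis$mean_flow)
  for (k in seq_along(basis$components)) {
    vec <- vec + coefficients[k] * flat_flow(basis$components[[k]])
  }
  unflat_flow(vec, basis$dims)
}

#' Project a flow field onto a basis
#'
#' Returns the coefficient vector of the mean-removed flow against the
#' orthonormal components (used to derive motion descriptors from
#' conventional optical-flow fields).
#'
#' @param basis A `flow_basis`.
#' @param flow A [flow_field()] on the basis grid.
#' @return Numeric vector of length `n_retained`.
#' @export
project_flow <- function(basis, flow) {
  if (basis$n_retained == 0L) return(numeric(0))
  resid <- flat_flow(flow) - flat_flow(basis$mean_flow)
  vapply(basis$components, function(cp) sum(resid * flat_flow(cp)), 0)
}

#' Estimate motion constrained to a learned PCA subspace
#'
#' Solves for coefficients `a` such that warping `moving` by
#' `mean_flow + sum_k a_k component_k` best matches `reference`, by
#' Gauss-Newton iterations on the linearized brightness-constancy residual,
#' spatially weighted by local gradient magnitude. Because the solution lives
#' in the low-dimensional breathing subspace, localized spurious deformation
#' (e.g. from heating-induced signal loss) cannot appear in the estimate.
#'
#' @param moving,reference Magnitude stacks of identical shape.
#' @param basis A [build_flow_basis()] result on the same grid.
#' @param params List with `n_gauss_newton` (default 10), `tolerance`
#'   (default 1e-4, on the coefficient update norm) and `score_bound`
#'   (default 3): each coefficient is bounded at `score_bound` times that
#'   component's learning-score standard deviation, so the estimate can
#'   never exceed the statistical range of motion seen during learning
#'   (set `Inf` to disable).
#' @return List with `flow` (a [flow_field()]) and `coefficients`.
#' @export
estimate_flow_pca <- function(moving, reference, basis,
                              params = list(n_gauss_newton = 10L,
                                            tolerance = 1e-4,
                                            score_bound = 3)) {
  moving <- as_3d(moving); reference <- as_3d(reference)
  stopifnot_same_dim(moving, reference, "moving and reference")
  if (!identical(dim(moving), basis$dims)) {
    stop("basis was built on a different grid", call. = FALSE)
  }
  bump_counter("pca")
  k <- basis$n_retained
  if (k == 0L) {
    warning("empty basis: returning mean flow")
    return(list(flow = basis$mean_flow, coefficients = numeric(0)))
  }
  nrm <- normalize_pair(moving, reference)
  mov <- nrm$moving; ref <- nrm$reference
  nvox <- prod(basis$dims)
  Cu <- vapply(basis$components, function(cp) as.vector(cp$u), numeric(nvox))
  Cv <- vapply(basis$components, function(cp) as.vector(cp$v), numeric(nvox))
  a <- numeric(k)
  ngn <- if (is.null(params$n_gauss_newton)) 10L else params$n_gauss_newton
  tol <- if (is.null(params$tolerance)) 1e-4 else params$tolerance
  bound <- if (is.null(params$score_bound)) 3 else params$score_bound
  for (it in seq_len(ngn)) {
    flow <- basis_flow(basis, a)
    w <- warp_image(mov, flow)
    nas <- is.na(w)
    if (any(nas)) w[nas] <- ref[nas]
    gx <- array(0, dim(w)); gy <- array(0, dim(w))
    for (s in seq_len(dim(w)[3])) {
      g <- image_gradient(w[, , s])
      gx[, , s] <- g$gx; gy[, , s] <- g$gy
    }
    r <- as.vector(w - ref)
    gxv <- as.vector(gx); gyv <- as.vector(gy)
    wgt <- sqrt(gxv^2 + gyv^2)
    J <- gxv * Cu + gyv * Cv          # nvox x k Jacobian
    JW <- J * wgt
    A <- crossprod(JW, J)
    b <- -crossprod(JW, r)
    A <- A + diag(1e-10 * max(diag(A), 1), k)
    da <- tryCatch(solve(A, b), error = function(e) rep(0, k))
    a <- a + as.vector(da)
    # motion cannot exceed the statistical range observed during learning:
    # bound each coefficient at +/- `score_bound` learning-score SDs
    if (!is.null(basis$score_sd) && is.finite(bound) && bound > 0) {
      lim <- bound * basis$score_sd
      a <- pmin(pmax(a, -lim), lim)
    }
    if (sqrt(sum(da^2)) < tol) break
  }
  list(flow = basis_flow(basis, a), coefficients = a)
}
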