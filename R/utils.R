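# Internal numeric helpers shared across modules.

#' Wrap phase into \eqn{[-\pi, \pi)}
#'
#' Maps arbitrary phase values (radians) onto the principal interval
#' \eqn{[-\pi, \pi)}. Idempotent.
#'
#' @param x Numeric vector/array of phase values in radians.
#' @return Object of the same shape with values in \eqn{[-\pi, \pi)}.
#' @export
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
wrap_phase <- function(x) {
  x - 2 * pi * floor((x + pi) / (2 * pi))
}

# Evaluate a 2D image at fractional (row, col) positions by bilinear
# interpolation. Positions outside [1, nr] x [1, nc] return NA.
# img: matrix; ri, ci: numeric vectors of equal length.
bilinear_sample <- function(img, ri, ci) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(ri))
  ok <- is.finite(ri) & is.finite(ci) &
    ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  if (!any(ok)) return(out)
  r <- ri[ok]; c <- ci[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  val <- (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i10] +
    (1 - fr) * fc * img[i01] + fr * fc * img[i11]
  out[ok] <- val
  out
}

# Warp one 2D slice by a pull-back displacement: out(i,j) = img(i + v, j + u).
# u: column displacement, v: row displacement (both matrices matching img).
warp_slice <- function(img, u, v) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- rep(seq_len(nr), times = nc) + as.vector(v)
  ci <- rep(seq_len(nc), each = nr) + as.vector(u)
  matrix(bilinear_sample(img, ri, ci), nr, nc)
}

# Bilinear resize of a 2D matrix to (nr2, nc2); used by the flow pyramid.
resize_bilinear <- function(img, nr2, nc2) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr2 == nr && nc2 == nc) return(img)
  # map output pixel centres onto input coordinates
  ri <- if (nr2 == 1) rep((nr + 1) / 2, 1) else 1 + (seq_len(nr2) - 1) * (nr - 1) / (nr2 - 1)
  ci <- if (nc2 == 1) rep((nc + 1) / 2, 1) else 1 + (seq_len(nc2) - 1) * (nc - 1) / (nc2 - 1)
  rg <- rep(ri, times = nc2)
  cg <- rep(ci, each = nr2)
  matrix(bilinear_sample(img, rg, cg), nr2, nc2)
}

# Central-difference spatial gradients of a 2D matrix (one-sided at borders).
# Returns list(gx = d/dcol, gy = d/drow).
image_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- img; gy <- img
  if (nc >= 3) {
    gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  }
  gx[, 1] <- img[, min(2, nc)] - img[, 1]
  gx[, nc] <- img[, nc] - img[, max(nc - 1, 1)]
  if (nr >= 3) {
    gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  }
  gy[1, ] <- img[min(2, nr), ] - img[1, ]
  gy[nr, ] <- img[nr, ] - img[max(nr - 1, 1), ]
  list(gx = gx, gy = gy)
}

# Weighted 8-neighbour local average used by the Horn-Schunck iteration
# (kernel 1/12 corners, 1/6 edges). Border handled by edge replication.
hs_local_average <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- rbind(m[1, , drop = FALSE], m, m[nr, , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, nc, drop = FALSE])
  ctr_r <- 2:(nr + 1); ctr_c <- 2:(nc + 1)
  (p[ctr_r - 1, ctr_c] + p[ctr_r + 1, ctr_c] +
     p[ctr_r, ctr_c - 1] + p[ctr_r, ctr_c + 1]) / 6 +
    (p[ctr_r - 1, ctr_c - 1] + p[ctr_r - 1, ctr_c + 1] +
       p[ctr_r + 1, ctr_c - 1] + p[ctr_r + 1, ctr_c + 1]) / 12
}

# Smooth a 2D matrix with a separable Gaussian (sd in pixels); used by the
# phantom generator to build smooth random fields.
gauss_smooth <- function(m, sd) {
  if (sd <= 0) return(m)
  half <- max(1L, ceiling(3 * sd))
  k <- exp(-((-half):half)^2 / (2 * sd^2))
  k <- k / sum(k)
  smooth_dim <- function(mm) {
    nr <- nrow(mm)
    pad <- rbind(mm[rep(1, half), , drop = FALSE], mm,
                 mm[rep(nr, half), , drop = FALSE])
    out <- matrix(0, nr, ncol(mm))
    for (i in seq_along(k)) {
      out <- out + k[i] * pad[i:(i + nr - 1), , drop = FALSE]
    }
    out
  }
  t(smooth_dim(t(smooth_dim(m))))
}

# Run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# shared argument checks ------------------------------------------------

stopifnot_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must share the same dimensions (got %s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Internal call counter used to assert that the standard workflow performs
# no registration (observability hook, see run_workflow).
.prftherm_counters <- new.env(parent = emptyenv())

bump_counter <- function(name) {
  cur <- if (exists(name, envir = .prftherm_counters)) {
    get(name, envir = .prftherm_counters)
  } else 0L
  assign(name, cur + 1L, envir = .prftherm_counters)
  invisible(cur + 1L)
}

#' Read an internal operation counter
#'
#' The flow-estimation routines increment named counters each time they run;
#' `flow_call_count()` exposes them so pipeline audits can assert, e.g., that
#' the standard (no-registration) workflow never estimated motion.
#'
#' @param name Counter name, `"hs"` or `"pca"`.
#' @param reset If `TRUE`, reset the counter to zero after reading.
#' @return Integer count.
#' @export
flow_call_count <- function(name = c("hs", "pca"), reset = FALSE) {
  name <- match.arg(name)
  cur <- if (exists(name, envir = .prftherm_counters)) {
    get(name, envir = .prftherm_counters)
  } else 0L
  if (reset) assign(name, 0L, envir = .prftherm_counters)
  cur
}
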