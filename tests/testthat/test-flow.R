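# Optical flow: Horn-Schunck, warping, reference selection, PCA basis and
# the subspace-constrained estimator.

test_that("flow on identical images is zero and zero-variance warns", {
  tmpl <- quiet_template()
  fl <- estimate_flow_hs(tmpl, tmpl)
  expect_lt(max(abs(fl$u), abs(fl$v)), 0.05)
  expect_warning(fl0 <- estimate_flow_hs(array(1, c(16, 16, 1)),
                                         array(1, c(16, 16, 1))),
                 "zero-variance")
  expect_equal(max(abs(fl0$u), abs(fl0$v)), 0)
  expect_error(estimate_flow_hs(array(NaN, c(8, 8, 1)),
                                array(1, c(8, 8, 1))), "non-finite")
})

test_that("Horn-Schunck recovers known translations of a smooth template", {
  tmpl <- quiet_template()
  g <- dim(tmpl)[1]
  interior <- round(0.15 * g):round(0.85 * g)
  for (shift in c(1, 2, 4)) {
    ref <- warp_image(tmpl, flow_field(matrix(shift, g, g), matrix(0, g, g)))
    ref[is.na(ref)] <- 0.05
    fl <- estimate_flow_hs(tmpl, ref)
    # oracle: the construction itself (integer shift of the template)
    expect_lt(abs(mean(fl$u[interior, interior, 1]) - shift), 0.2)
    expect_lt(abs(mean(fl$v[interior, interior, 1])), 0.1)
  }
})

test_that("heating-like signal dropout induces spurious Horn-Schunck flow", {
  # ground truth is the zero field: any estimated flow is error
  tmpl <- quiet_template()
  g <- dim(tmpl)[1]
  rr <- matrix(seq_len(g), g, g); cc <- t(rr)
  disc <- exp(-((rr - g / 2)^2 + (cc - g / 2)^2) / (2 * 3^2))
  dropped <- tmpl
  dropped[, , 1] <- tmpl[, , 1] * (1 - 0.5 * disc)
  fl <- estimate_flow_hs(dropped, tmpl)
  ee <- sqrt(fl$u^2 + fl$v^2)
  expect_gt(max(ee[disc > 0.1]), 0.5)
})

test_that("warping obeys identity, shift, approximate-inverse and linearity", {
  tmpl <- quiet_template()
  g <- dim(tmpl)[1]
  zero <- flow_field(matrix(0, g, g), matrix(0, g, g))
  expect_equal(warp_image(tmpl, zero), tmpl)
  # constant integer flow shifts by one column
  one <- flow_field(matrix(1, g, g), matrix(0, g, g))
  w <- warp_image(tmpl, one)
  expect_equal(w[, 1:(g - 1), 1], tmpl[, 2:g, 1])
  expect_true(all(is.na(w[, g, 1])))  # out of bounds marked invalid
  # warp by F then -F returns close to the original in the interior
  set.seed(4)
  Fsm <- flow_field(
    array(gauss_smooth(matrix(rnorm(g * g), g, g), 8) * 5, c(g, g, 1)),
    array(gauss_smooth(matrix(rnorm(g * g), g, g), 8) * 5, c(g, g, 1)))
  there <- warp_image(tmpl, Fsm)
  back <- warp_image(there, flow_field(-Fsm$u, -Fsm$v))
  interior <- 10:(g - 10)
  resid <- (back - tmpl)[interior, interior, 1]
  expect_lt(sqrt(mean(resid^2, na.rm = TRUE)), 0.05 * diff(range(tmpl)))
  # linearity in the image argument
  a <- tmpl; b <- tmpl[g:1, , , drop = FALSE]
  lhs <- warp_image(2 * a + 3 * b, Fsm)
  rhs <- 2 * warp_image(a, Fsm) + 3 * warp_image(b, Fsm)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("complex warping preserves unit magnitude of pure phase", {
  g <- 32
  ph <- gauss_smooth(matrix(rnorm(g * g), g, g), 6)
  cm <- array(exp(1i * ph), c(g, g, 1))
  fl <- flow_field(matrix(0.5, g, g), matrix(0.5, g, g))
  w <- warp_image(cm, fl)
  expect_lt(max(abs(Mod(w) - 1), na.rm = TRUE), 0.05)
})

test_that("reference frame selection returns the lower-median position", {
  tmpl <- quiet_template()
  g <- dim(tmpl)[1]
  # frames at known positions 0, 0.1, ..., 0.9 voxels along columns
  shifts <- seq(0, 0.9, by = 0.1)
  mag <- array(0, c(g, g, 1, 10))
  for (i in seq_along(shifts)) {
    f <- warp_image(tmpl, flow_field(matrix(shifts[i], g, g), matrix(0, g, g)))
    f[is.na(f)] <- 0.05
    mag[, , , i] <- f
  }
  s <- dynamic_series(mag, array(0, dim(mag)), 0:9)
  idx <- select_reference_frame(s, 10)
  # oracle: sort the 10 positions, take the 5th (lower median).
  # positions relative to frame 1 are -shifts, whose 5th smallest is -0.5,
  # i.e. the frame shifted by 0.5 voxels
  expect_equal(idx, 6L)
  # all frames identical: earliest tied frame wins
  mag2 <- array(rep(tmpl, 12), c(g, g, 1, 12))
  s2 <- dynamic_series(mag2, array(0, dim(mag2)), 0:11)
  expect_equal(select_reference_frame(s2, 10), 1L)
  expect_error(select_reference_frame(s2, 2), ">= 3")
})

test_that("flow basis recovers rank and variance structure", {
  dims <- c(16, 16, 1)
  base_u <- array(gauss_smooth(matrix(rnorm(256), 16, 16), 4), dims)
  base_v <- array(gauss_smooth(matrix(rnorm(256), 16, 16), 4), dims)
  F1 <- flow_field(base_u, base_v)
  # rank-1 family: a_i * F
  flows <- lapply(c(0.5, 1, 1.5, 2, 3), function(a)
    flow_field(a * F1$u, a * F1$v))
  b1 <- build_flow_basis(flows)
  expect_equal(b1$n_retained, 1L)
  expect_gt(b1$explained_variance[1], 0.999)
  # component is proportional to F (up to sign)
  c1 <- b1$components[[1]]
  corr <- abs(sum(c1$u * F1$u + c1$v * F1$v)) /
    sqrt(sum(c1$u^2 + c1$v^2) * sum(F1$u^2 + F1$v^2))
  expect_gt(corr, 0.999)

  # two orthogonal patterns with known weight variances
  set.seed(11)
  U2 <- array(0, dims); V2 <- array(0, dims)
  U2[1:8, , 1] <- 1; V2[9:16, , 1] <- 1      # disjoint supports: orthogonal
  n2 <- sqrt(sum(U2^2) + sum(V2^2))
  F2 <- flow_field(U2 / n2, V2 / n2)
  F1n <- flow_field(array(0, dims), array(0, dims))
  F1n$v[1:8, , 1] <- 1; F1n$v <- F1n$v / sqrt(sum(F1n$v^2))
  a <- rnorm(15, sd = 2); b <- rnorm(15, sd = 0.5)
  flows2 <- lapply(1:15, function(i)
    flow_field(a[i] * F2$u, a[i] * F2$v + b[i] * F1n$v))
  b2 <- build_flow_basis(flows2, variance_threshold = 0.999)
  expect_equal(b2$n_retained, 2L)
  # oracle: eigenvalues of the 2x2 coefficient covariance
  ev_oracle <- eigen(stats::cov(cbind(a, b)))$values
  expect_equal(b2$explained_variance, ev_oracle / sum(ev_oracle),
               tolerance = 1e-6)

  # degenerate case: identical flows
  same <- lapply(1:15, function(i) F1)
  expect_warning(b3 <- build_flow_basis(same), "zero components")
  expect_equal(b3$n_retained, 0L)
  expect_equal(b3$mean_flow$u, F1$u)
})

test_that("PCA-constrained flow recovers an in-span coefficient", {
  gen <- generate_series(phantom_config(grid = c(64, 64, 2), n_frames = 40,
                                        displacement_amplitude = 4,
                                        noise_sd = 0, seed = 11))
  tmpl <- gen$truth$template
  dispn <- vapply(gen$truth$displacements, function(d) max(abs(d$v)), 0)
  basis <- build_flow_basis(gen$truth$displacements[which(dispn > 0.1)[1:10]])
  a_true <- c(1.5, rep(0, basis$n_retained - 1))[seq_len(basis$n_retained)]
  ref <- warp_image(tmpl, basis_flow(basis, a_true))
  ref[is.na(ref)] <- 0.05
  est <- estimate_flow_pca(tmpl, ref, basis)
  expect_lt(abs(est$coefficients[1] - 1.5), 0.1)
  aee <- endpoint_error(est$flow, basis_flow(basis, a_true))$aee
  expect_lt(aee, 0.1)
  # solution lies exactly in the basis span
  recon <- basis_flow(basis, est$coefficients)
  expect_lt(max(abs(est$flow$u - recon$u), abs(est$flow$v - recon$v)), 1e-10)
})

test_that("empty basis falls back to the mean flow", {
  tmpl <- quiet_template(c(32, 32, 1), seed = 13)
  mean_only <- structure(list(
    mean_flow = flow_field(array(0.3, c(32, 32, 1)), array(0, c(32, 32, 1))),
    components = list(), explained_variance = numeric(0),
    score_sd = numeric(0), n_retained = 0L, dims = c(32L, 32L, 1L)),
    class = "flow_basis")
  expect_warning(est <- estimate_flow_pca(tmpl, tmpl, mean_only), "empty")
  expect_equal(est$flow$u, mean_only$mean_flow$u)
  expect_length(est$coefficients, 0)
  expect_length(project_flow(mean_only, mean_only$mean_flow), 0)
})

test_that("in-subspace motion gives agreeing PCA and Horn-Schunck flows", {
  gen <- generate_series(phantom_config(grid = c(64, 64, 1), n_frames = 40,
                                        displacement_amplitude = 3,
                                        noise_sd = 0, seed = 21))
  tmpl <- gen$truth$template
  dispn <- vapply(gen$truth$displacements, function(d) max(abs(d$v)), 0)
  basis <- build_flow_basis(gen$truth$displacements[which(dispn > 0.1)[1:10]])
  # a frame with genuine in-span motion, no intensity perturbation
  target <- gen$truth$displacements[[which.max(dispn)]]
  mov <- warp_image(tmpl, flow_field(-target$u, -target$v))
  mov[is.na(mov)] <- 0.05
  hs <- estimate_flow_hs(mov, tmpl)
  pca <- estimate_flow_pca(mov, tmpl, basis)$flow
  body <- gen$truth$body_mask
  aee <- mean(sqrt((hs$u - pca$u)^2 + (hs$v - pca$v)^2)[body])
  expect_lt(aee, 0.2)
})
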