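# PRF temperature conversion, unwrapping, drift correction, filtering.

test_that("the degrees-per-radian factor matches direct arithmetic", {
  # oracle: 1 / (2*pi * 42.58e6 * (-0.0094e-6) * 0.018 * 1.5) degC per rad
  oracle <- 1 / (2 * pi * 42.58e6 * (-0.0094e-6) * 0.018 * 1.5)
  expect_equal(1 / prf_phase_factor(thermo_params()), oracle,
               tolerance = 1e-12)
  expect_lt(oracle, 0)  # heating decreases phase
})

test_that("forward PRF phase inverts exactly", {
  set.seed(41)
  tp <- thermo_params()
  dT <- array(runif(16 * 16 * 2, -40, 40), c(16, 16, 2))
  phi_ref <- array(runif(16 * 16 * 2, -pi, pi), c(16, 16, 2))
  phi_t <- wrap_phase(phi_ref + prf_phase_factor(tp) * dT)
  rec <- phase_to_temperature(phi_t, phi_ref, tp)
  expect_lt(max(abs(rec - dT)), 1e-9)
  # identical phases give zero and the exact +10 degC phase gives 10.000
  expect_equal(max(abs(phase_to_temperature(phi_ref, phi_ref, tp))), 0)
  d10 <- phase_to_temperature(wrap_phase(phi_ref + prf_phase_factor(tp) * 10),
                              phi_ref, tp)
  expect_equal(max(abs(d10 - 10)), 0, tolerance = 1e-9)
  expect_error(thermo_params(te = 0), "te")
  expect_error(thermo_params(b0 = -1), "b0")
  expect_error(thermo_params(sigma = 0.0094), "negative")
})

test_that("small phase perturbations scale linearly through the conversion", {
  tp <- thermo_params()
  phi <- array(runif(64, -1, 1), c(8, 8, 1))
  ref <- array(0, c(8, 8, 1))
  delta <- 0.01
  diffT <- phase_to_temperature(phi + delta, ref, tp) -
    phase_to_temperature(phi, ref, tp)
  expect_equal(diffT, array(delta / prf_phase_factor(tp), c(8, 8, 1)),
               tolerance = 1e-9)
})

test_that("temporal unwrapping removes 2*pi jumps and survives a 60-degree ramp", {
  x <- seq(0, 2, length.out = 100)
  expect_equal(temporal_unwrap(x), x)  # no wraps: unchanged
  y <- x; y[50:100] <- y[50:100] + 2 * pi
  expect_equal(temporal_unwrap(wrap_phase(y)), x, tolerance = 1e-9)
  # 60 degC ramp wraps once at the default PRF parameters
  tp <- thermo_params()
  dT_true <- seq(0, 60, length.out = 80)
  phi <- wrap_phase(prf_phase_factor(tp) * dT_true)
  rec <- temporal_unwrap(phi) / prf_phase_factor(tp)
  expect_lt(max(abs(rec - dT_true)), 1e-9)
})

test_that("drift correction removes injected drift without touching clean maps", {
  set.seed(42)
  d <- c(24, 24, 1, 20)
  base <- array(rnorm(prod(d), sd = 0.05), d)
  # clean input barely changes
  out0 <- drift_correct(base)
  expect_lt(max(abs(out0 - base)), 0.2)
  # spatially uniform drift of 0.02 degC/frame
  drifted <- base
  for (t in 1:20) drifted[, , , t] <- drifted[, , , t] + 0.02 * (t - 1)
  out1 <- drift_correct(drifted)
  resid_slope <- coef(lm(m ~ t, data.frame(
    t = 1:20, m = apply(out1, 4, mean))))[2]
  expect_lt(abs(resid_slope), 0.002)
  # linear spatial ramp removed below 0.2 degC
  ramp <- outer(seq(0, 2, length.out = 24), rep(1, 24))
  ramped <- base
  for (t in 1:20) ramped[, , , t] <- ramped[, , , t] + ramp
  out2 <- drift_correct(ramped)
  expect_lt(max(abs(out2 - out0)), 0.2)
  # too few unheated voxels: left untouched with a warning
  hot <- array(TRUE, d); hot[1:3, 1:3, , ] <- FALSE
  expect_warning(out3 <- drift_correct(drifted, hot), "fewer than")
  expect_equal(out3, drifted)
})

test_that("heated voxels are excluded cumulatively from the drift fit", {
  d <- c(8, 8, 1, 4)
  x <- array(0, d)
  x[4, 4, 1, 2] <- 5   # heats at frame 2, cools after
  hm <- cumulative_heated_mask(x, 3)
  expect_false(hm[4, 4, 1, 1])
  expect_true(hm[4, 4, 1, 2])
  expect_true(hm[4, 4, 1, 4])  # stays excluded once heated
})

test_that("the causal Butterworth filter matches its analytic response", {
  # DC gain 1 after the transient
  const <- rep(3, 200)
  y <- lowpass_filter(const, 0.14, 2)
  expect_equal(tail(y, 1), 3, tolerance = 1e-6)
  gain_at <- function(f, dt) {
    n <- 2000; t <- (0:(n - 1)) * dt
    y <- lowpass_filter(sin(2 * pi * f * t), 0.14, dt)
    idx <- (n / 2):n
    X <- cbind(sin(2 * pi * f * t[idx]), cos(2 * pi * f * t[idx]))
    sqrt(sum(qr.coef(qr(X), y[idx])^2))
  }
  # half-power point: |H(0.14)| = 1/sqrt(2) at 2 s sampling
  expect_equal(gain_at(0.14, 2), 1 / sqrt(2), tolerance = 0.02)
  # off-cutoff attenuation matches 1/sqrt(1+(f/fc)^2) within 3%
  expect_equal(gain_at(0.25, 0.5), 1 / sqrt(1 + (0.25 / 0.14)^2),
               tolerance = 0.03)
  expect_error(lowpass_filter(1:10, 0.3, 2), "Nyquist")
})

test_that("the filter is causal", {
  set.seed(43)
  x <- rnorm(100)
  y1 <- lowpass_filter(x, 0.14, 2)
  x2 <- x; x2[61:100] <- x2[61:100] + 10  # perturb the future
  y2 <- lowpass_filter(x2, 0.14, 2)
  expect_equal(y1[1:60], y2[1:60])
  expect_false(isTRUE(all.equal(y1[61:100], y2[61:100])))
})
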