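# Phantom generator: determinism, motion model, forward PRF consistency,
# acquisition-regime presets.

test_that("same seed gives bit-identical series, different seeds differ", {
  cfg <- phantom_config(grid = c(24, 24, 1), n_frames = 20, seed = 5)
  a <- generate_series(cfg)
  b <- generate_series(cfg)
  expect_identical(a$series$magnitude, b$series$magnitude)
  expect_identical(a$series$phase, b$series$phase)
  cfg2 <- phantom_config(grid = c(24, 24, 1), n_frames = 20, seed = 6)
  c <- generate_series(cfg2)
  expect_false(identical(a$series$magnitude, c$series$magnitude))
})

test_that("static configuration yields identical frames", {
  cfg <- phantom_config(grid = c(24, 24, 1), n_frames = 20,
                        displacement_amplitude = 0, noise_sd = 0,
                        peak_delta_t = 0, drift_rate = 0, seed = 3)
  gen <- generate_series(cfg)
  for (t in 2:20) {
    expect_equal(gen$series$magnitude[, , , t], gen$series$magnitude[, , , 1])
    expect_equal(gen$series$phase[, , , t], gen$series$phase[, , , 1])
  }
})

test_that("phase subtraction at the true reference inverts to the true temperature", {
  # motionless, noise-free: wrap(phi_t - phi_1) through the PRF relation
  # must reproduce the generated temperature below the wrap limit
  cfg <- phantom_config(grid = c(32, 32, 1), n_frames = 30,
                        displacement_amplitude = 0, noise_sd = 0,
                        drift_rate = 0, max_signal_drop = 0,
                        peak_delta_t = 40, heating_window = c(16, 28),
                        seed = 9)
  gen <- generate_series(cfg)
  tp <- thermo_params(te = cfg$te, b0 = cfg$b0)
  for (t in c(20, 28)) {
    dT <- phase_to_temperature(gen$series$phase[, , , t],
                               gen$series$phase[, , , 1], tp)
    expect_lt(max(abs(dT - gen$truth$delta_t[, , , t])), 1e-6)
  }
})

test_that("respiratory profile has the analytic cycle mean 3/8", {
  tgrid <- seq(0, 4.5, length.out = 20001)[-20001]
  expect_equal(mean(resp_profile(tgrid, 4.5)), 3 / 8, tolerance = 1e-4)
  expect_true(all(resp_profile(tgrid, 4.5) >= 0 &
                    resp_profile(tgrid, 4.5) <= 1))
  # fixed-frequency breathing positions follow amplitude * profile exactly
  cfg <- phantom_config(grid = c(24, 24, 1), n_frames = 20,
                        displacement_amplitude = 4, seed = 2)
  gen <- generate_series(cfg)
  expect_equal(gen$truth$s,
               4 * resp_profile(gen$series$timestamps, cfg$respiratory_period))
})

test_that("image similarity matches the acquisition regimes", {
  # gated sampling freezes motion: intercorrelation vs reference > 0.95;
  # fixed-frequency sampling breathes through the cycle but stays > 0.9
  gcfg <- preset_config("gated_paper", grid = c(128, 128, 1), n_frames = 24,
                        heating_window = c(16, 22))
  g <- generate_series(gcfg)
  ic_g <- vapply(2:24, function(t)
    intercorrelation(g$series$magnitude[, , , t],
                     g$series$magnitude[, , , 1]), 0)
  expect_gt(min(ic_g), 0.95)

  fcfg <- preset_config("fixed_frequency_paper", grid = c(128, 128, 1),
                        n_frames = 24, heating_window = c(16, 22))
  f <- generate_series(fcfg)
  ref <- select_reference_frame(f$series, 10)
  ic_f <- vapply(setdiff(1:24, ref), function(t)
    intercorrelation(f$series$magnitude[, , , t],
                     f$series$magnitude[, , , ref]), 0)
  expect_gt(min(ic_f), 0.9)
  expect_lt(min(ic_f), min(ic_g))  # breathing lowers similarity
})

test_that("presets encode the acquisition regimes", {
  ff <- preset_config("fixed_frequency_paper")
  expect_equal(ff$frame_interval, 2.0)
  expect_equal(ff$peak_delta_t, 50)
  expect_gte(ff$grid[3], 13)
  g <- preset_config("gated_paper")
  expect_true(g$frame_interval >= 3.5 && g$frame_interval <= 5)
  expect_equal(g$mode, "gated")
  expect_equal(g$displacement_amplitude, 0)  # gating freezes bulk motion
  expect_error(preset_config("nope"), "gated_paper")
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(n_frames = 10), ">= 20")
  expect_error(phantom_config(max_signal_drop = 1.5), "\\[0, 1\\]")
  expect_error(phantom_config(displacement_amplitude = -1), ">= 0")
  expect_error(phantom_config(heating_window = c(0, 10)), "heating_window")
  expect_error(phantom_config(n_frames = 30, heating_window = c(16, 40)),
               "heating_window")
})
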