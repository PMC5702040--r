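test_that("spherical propagation loss matches its closed form", {
  expect_equal(propagation_loss_spherical(1), 0)
  expect_equal(propagation_loss_spherical(1000), 60)
  expect_equal(propagation_loss_spherical(456), 20 * log10(456))
  expect_equal(propagation_loss_spherical(456), 53.18, tolerance = 1e-3)
  expect_equal(propagation_loss_spherical(1000, absorption_dB_per_km = 0.1),
               60.1)
  expect_error(propagation_loss_spherical(0), "range")
  expect_error(propagation_loss_spherical(-5), "range")
})

test_that("doubling the range lowers spherical-PL SPL by exactly 6.021 dB", {
  r <- c(10, 123, 456, 2000, 98765)
  drop <- propagation_loss_spherical(2 * r) - propagation_loss_spherical(r)
  expect_equal(drop, rep(20 * log10(2), 5), tolerance = 1e-12)
  expect_equal(20 * log10(2), 6.021, tolerance = 1e-3)
})

test_that("slant range is the 3-D Euclidean distance", {
  expect_equal(slant_range(c(0, 0, 50), c(0, 0, 0)), 50)
  expect_equal(slant_range(c(0, 0, 50), c(300, 0, 50)), 300)
  expect_equal(slant_range(c(0, 0, 50), c(10, 0, 0)), sqrt(2600))
  expect_equal(slant_range(c(0, 0, 50), c(10, 0, 0)), 50.99, tolerance = 1e-3)
  expect_error(slant_range(c(1, 2, 3), c(1, 2, 3)), "coincide")
})

test_that("a PL grid interpolates bilinearly and clamps at its edges", {
  grid <- expand.grid(range_m = c(100, 200), depth_m = c(0, 50))
  grid$PL_dB <- 40 + 0.1 * grid$range_m + 0.2 * grid$depth_m  # bilinear field
  pl <- pl_grid(grid)
  expect_equal(pl(150, 25), 40 + 15 + 5)
  expect_equal(pl(100, 0), 50)
  expect_equal(pl(5000, 25), 40 + 20 + 5)     # clamped to range edge
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(grid, path)
  expect_equal(read_pl_grid(path)(150, 25), pl(150, 25))
})

test_that("single-pulse exposure matches the hand geometry oracle", {
  ship <- stationary_whale(0, 0, depth = 50)
  whale <- stationary_whale(456, 0, depth = 0)
  sch <- as_test_scheme(data.frame(time_s = 300, SL_dB = 214, duration_s = 1,
                                   effective_duration_s = 0.93))
  res <- compute_exposure(sch, ship, whale)
  slant <- sqrt(456^2 + 50^2)
  pl <- 20 * log10(slant)
  expect_equal(res$pulses$slant_range_m, slant, tolerance = 1e-9)
  expect_equal(res$pulses$SPL_dB, 214 - pl, tolerance = 1e-9)
  expect_equal(res$indicators$SPL_max_dB, 160.77, tolerance = 1e-2)
  expect_equal(res$indicators$SEL_cum_dB, 214 + 10 * log10(0.93) - pl,
               tolerance = 1e-9)
  expect_equal(res$indicators$SEL_cum_dB, 160.45, tolerance = 1e-2)
  # one pulse: SEL_cum equals the single-pulse SEL
  expect_equal(res$indicators$SEL_cum_dB, res$pulses$SEL_dB)
  expect_equal(res$pulses$E_uPa2s, 10^(res$pulses$SEL_dB / 10))
})

test_that("two equal-range pulses add 3.010 dB to SEL_cum, not to SPL_max", {
  ship <- stationary_whale(0, 0, depth = 50)
  whale <- stationary_whale(456, 0, depth = 0)
  one <- as_test_scheme(data.frame(time_s = 0, SL_dB = 214, duration_s = 1,
                                   effective_duration_s = 0.93))
  two <- as_test_scheme(data.frame(time_s = c(0, 20), SL_dB = 214,
                                   duration_s = 1, effective_duration_s = 0.93))
  r1 <- compute_exposure(one, ship, whale)
  r2 <- compute_exposure(two, ship, whale)
  expect_equal(r2$indicators$SEL_cum_dB,
               r1$indicators$SEL_cum_dB + 10 * log10(2), tolerance = 1e-12)
  expect_equal(r2$indicators$SPL_max_dB, r1$indicators$SPL_max_dB)
})

test_that("SEL_cum is permutation-invariant and non-decreasing in pulses", {
  ship <- straight_ship()
  whale <- stationary_whale(200, 800)
  sch <- build_ramp_up_scheme()
  res <- compute_exposure(sch, ship, whale)
  expect_gte(res$indicators$SEL_cum_dB, max(res$pulses$SEL_dB))
  # dropping pulses can only lower SEL_cum
  sub <- as_test_scheme(as.data.frame(sch[1:10, ]))
  expect_lt(compute_exposure(sub, ship, whale)$indicators$SEL_cum_dB,
            res$indicators$SEL_cum_dB)
  # permutation: energy sum independent of pulse order
  expect_equal(res$indicators$SEL_cum_dB,
               10 * log10(sum(sample(res$pulses$E_uPa2s))), tolerance = 1e-12)
})

test_that("a control scheme yields absent levels but a valid R_min", {
  ship <- straight_ship()
  whale <- stationary_whale(456, 1230)
  res <- compute_exposure(build_control_scheme(), ship, whale)
  expect_true(is.na(res$indicators$SPL_max_dB))
  expect_true(is.na(res$indicators$SEL_cum_dB))
  expect_gt(res$indicators$R_min_m, 0)
  # R_min does not depend on the scheme
  res_fp <- compute_exposure(build_full_power_scheme(), ship, whale)
  expect_equal(res$indicators$R_min_m, res_fp$indicators$R_min_m)
})

test_that("R_min is evaluated between pulse times at 1 s resolution", {
  ship <- straight_ship()
  # whale abeam of the track at the ship's y position at t = 310 s (between
  # pulses at 300 and 320): closest approach falls between pulse times
  whale <- stationary_whale(100, 4.1 * 310)
  res <- compute_exposure(build_full_power_scheme(), ship, whale)
  expect_lt(res$indicators$R_min_m, min(res$pulses$slant_range_m))
  expect_equal(res$indicators$R_min_m, sqrt(100^2 + 50^2), tolerance = 0.1)
})

test_that("a stationary whale on the trackline peaks at minimum slant range", {
  ship <- straight_ship()
  whale <- stationary_whale(0, 1500, depth = 0)
  res <- compute_exposure(build_full_power_scheme(), ship, whale)
  expect_equal(which.max(res$pulses$SPL_dB),
               which.min(res$pulses$slant_range_m))
})

test_that("a very distant whale receives SL minus spherical PL", {
  ship <- straight_ship()
  whale <- stationary_whale(100e3, 0)
  res <- compute_exposure(build_full_power_scheme(), ship, whale)
  expect_equal(res$indicators$SPL_max_dB, 214 - 100, tolerance = 0.01)
})

test_that("pulse times outside the track span raise a named error", {
  ship <- straight_ship(t0 = 0, t1 = 400)
  whale <- stationary_whale(456, 0)
  expect_error(compute_exposure(build_full_power_scheme(), ship, whale,
                                session_window = c(0, 400)),
               "ship track")
})

test_that("modelled full-power outcomes reuse the observed tracks", {
  exp <- make_experiment(seed = 14)
  ctrl <- exp$sessions[[1]]
  res <- simulate_fullpower_outcome(ctrl, whale_track = exp$whale_track)
  expect_equal(res$indicators$n_pulses, 15)
  direct <- compute_exposure(build_full_power_scheme(), ctrl$ship_track,
                             exp$whale_track, session_start_s = ctrl$start_s,
                             session_window = c(ctrl$start_s, ctrl$end_s))
  expect_equal(res$indicators, direct$indicators)
})

test_that("bias correction centres modelled levels on measurements", {
  out <- apply_bias_correction(c(100, 102), measured = c(105.8, 107.8))
  expect_equal(attr(out, "offset_dB"), 5.8)
  expect_equal(as.numeric(out), c(105.8, 107.8))
  expect_equal(mean(out - c(105.8, 107.8)), 0)
  expect_equal(as.numeric(apply_bias_correction(c(1, 2, 3), offset = 0)),
               c(1, 2, 3))
  expect_equal(as.numeric(apply_bias_correction(c(170, 175), offset = 2.2)),
               c(172.2, 177.2))
  expect_error(apply_bias_correction(c(1, 2), measured = c(1, 2, 3)), "paired")
  expect_error(apply_bias_correction(c(1, 2)), "supply")
})

test_that("the ramp-up SEL_cum adjustment subtracts 0.43 dB exactly once", {
  x <- adjust_rampup_selcum(180, "RampUp1")
  expect_equal(as.numeric(x), 179.57)
  expect_warning(y <- adjust_rampup_selcum(x, "RampUp1"), "already")
  expect_equal(as.numeric(y), 179.57)
  expect_warning(z <- adjust_rampup_selcum(180, "FullPower"), "non-ramp-up")
  expect_equal(as.numeric(z), 180)
})

test_that("position uncertainty propagates monotonically into level spread", {
  ship <- straight_ship()
  whale <- stationary_whale(300, 600)
  sch <- build_full_power_scheme()
  zero <- propagate_position_uncertainty(sch, ship, whale, horiz_sd_m = 0,
                                         depth_sd_m = 0, n_draws = 5, seed = 1)
  expect_equal(zero$summary$sd, c(0, 0))
  small <- propagate_position_uncertainty(sch, ship, whale, horiz_sd_m = 5,
                                          n_draws = 60, seed = 2)
  large <- propagate_position_uncertainty(sch, ship, whale, horiz_sd_m = 80,
                                          n_draws = 60, seed = 2)
  expect_true(all(large$summary$sd > small$summary$sd))
  expect_error(propagate_position_uncertainty(sch, ship, whale, -1), "negative")
})
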