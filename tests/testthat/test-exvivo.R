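test_that("bubble velocity is the least-squares slope of the track", {
  v <- estimate_bubble_velocity(c(0, 600, 1200), c(0, 6e-5, 1.2e-4))
  expect_equal(v$velocity, 1.0e-7, tolerance = 1e-12)
  expect_equal(v$stderr, 0, tolerance = 1e-15)

  v0 <- estimate_bubble_velocity(c(0, 600, 1200), c(0, 0, 0))
  expect_equal(v0$velocity, 0)

  t4 <- c(0, 600, 1200, 1800)
  x4 <- c(0, 5.5e-5, 1.25e-4, 1.79e-4)
  ref <- ols_oracle(t4, x4)
  v4 <- estimate_bubble_velocity(t4, x4)
  expect_equal(v4$velocity, ref$slope, tolerance = 1e-12)
  expect_equal(v4$stderr, ref$se_slope, tolerance = 1e-10)
})

test_that("velocity estimation rejects degenerate inputs", {
  expect_error(estimate_bubble_velocity(c(0, 600), c(0, 1e-5)),
               "at least 3")
  expect_error(estimate_bubble_velocity(c(0, 0, 600), c(0, 1e-5, 2e-5)),
               "strictly increasing")
})

test_that("nominal conductivity follows the chamber Darcy formula", {
  m <- ussing_measurement("a", c(0, 600, 1200), c(0, 6e-5, 1.2e-4))
  # independent arithmetic: (b/d)^2 w v / (rho g h)
  expected <- (1e-3 / 5.05e-3)^2 * 1e-3 * 1e-7 / (998 * 9.81 * 0.16)
  expect_equal(nominal_conductivity(m, 1e-7), expected, tolerance = 1e-12)
  expect_equal(expected, 2.50e-15, tolerance = 2e-3)  # magnitude check
  expect_equal(nominal_conductivity(m, 0), 0)
})

test_that("nominal conductivity scaling symmetries hold", {
  base <- ussing_measurement("a", c(0, 600, 1200), c(0, 6e-5, 1.2e-4))
  K0 <- nominal_conductivity(base, 1e-7)
  m_b2 <- ussing_measurement("a", base$times, base$positions, b = 2e-3)
  expect_equal(nominal_conductivity(m_b2, 1e-7), 4 * K0)
  m_d2 <- ussing_measurement("a", base$times, base$positions, d = 2 * 5.05e-3)
  expect_equal(nominal_conductivity(m_d2, 1e-7), K0 / 4)
  m_bd <- ussing_measurement("a", base$times, base$positions,
                             b = 3e-3, d = 3 * 5.05e-3)
  expect_equal(nominal_conductivity(m_bd, 1e-7), K0)
  # linear in velocity and thickness
  expect_equal(nominal_conductivity(base, 2e-7), 2 * K0)
  m_w2 <- ussing_measurement("a", base$times, base$positions, w = 2e-3)
  expect_equal(nominal_conductivity(m_w2, 1e-7), 2 * K0)
})

test_that("negative velocity is flagged, zero head rejected", {
  m <- ussing_measurement("a", c(0, 600, 1200), c(0, 6e-5, 1.2e-4))
  expect_warning(Kn <- nominal_conductivity(m, -1e-7), "leak")
  expect_lt(Kn, 0)
  expect_error(ussing_measurement("a", c(0, 600, 1200),
                                  c(0, 6e-5, 1.2e-4), h = 0),
               "positive")
})

test_that("PBS viscosity interpolates the tabulated anchors", {
  expect_equal(pbs_viscosity(18), 1.1e-3)
  expect_equal(pbs_viscosity(25), 8.9e-4)
  expect_equal(pbs_viscosity(21.5), (1.1e-3 + 8.9e-4) / 2)
  expect_warning(pbs_viscosity(30), "extrapolating")
})

test_that("viscosity correction rescales by the viscosity ratio", {
  expect_equal(viscosity_correct(1e-14, 8.9e-4, 3.5e-3),
               1e-14 * 8.9e-4 / 3.5e-3, tolerance = 1e-12)
  expect_equal(1e-14 * 8.9e-4 / 3.5e-3, 2.543e-15, tolerance = 1e-3)
  expect_equal(viscosity_correct(1e-14, 2e-3, 2e-3), 1e-14)
  expect_equal(viscosity_correct(0, 8.9e-4, 3.5e-3), 0)
  expect_error(viscosity_correct(1e-14, 8.9e-4, 0), "positive")
})

test_that("full chain output stays in the physical envelope", {
  m <- ussing_measurement("a", c(0, 600, 1200), c(0, 6e-5, 1.2e-4))
  for (v in 10^seq(-9, -6, by = 0.5)) {
    Kn <- nominal_conductivity(m, v)
    K <- viscosity_correct(Kn, pbs_viscosity(21), 3.5e-3)
    expect_gt(K, 1e-16 * v / 1e-9 * 1e-3)  # loose lower scale
    expect_true(K >= 1e-18 && K <= 1e-12)
  }
})

test_that("measurement round trip recovers the injected conductivity", {
  for (seed in 1:20) {
    m0 <- generate_bubble_track(7.3e-15, noise_sd_position = 0,
                                seed = seed)
    r0 <- suppressWarnings(measure_conductivity(m0))
    expect_equal(r0$K_corrected, 7.3e-15, tolerance = 1e-12)

    m <- generate_bubble_track(7.3e-15, noise_sd_position = 5e-6,
                               seed = seed)
    r <- measure_conductivity(m)
    seK <- r$K_corrected * r$velocity_stderr / r$velocity
    expect_lt(abs(r$K_corrected - 7.3e-15), 5 * seK)
  }
})

test_that("bubble-track CSV round trips through the reader", {
  m <- generate_bubble_track(5e-15, seed = 11, temperature_C = 20)
  df <- data.frame(sample_id = m$sample_id, time_s = m$times,
                   position_m = m$positions, temperature_C = 20)
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  write.csv(df, tf, row.names = FALSE)
  tracks <- read_bubble_tracks(tf)
  expect_length(tracks, 1)
  tab <- conductivity_table(tracks)
  expect_equal(tab$K_corrected,
               measure_conductivity(m)$K_corrected, tolerance = 1e-10)
  expect_named(tab, c("sample_id", "velocity", "velocity_stderr",
                      "K_nominal", "K_corrected", "mu_pbs", "mu_if",
                      "leak_suspect"))
})
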