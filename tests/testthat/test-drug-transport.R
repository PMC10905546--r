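geo <- tumor_geometry()
grid <- radial_grid(geo, 400)
par <- transport_params()

test_that("Peclet number and exchange terms follow their formulas", {
  dp <- drug_params(Ld = 1e-8, sigma_d = 0.9)
  expect_equal(peclet_field(0, dp, 1e4), 0)
  expect_equal(peclet_field(1e-4, dp, 1e4), 1e-4 * 0.1 / 1e-4)
  dp1 <- drug_params(Ld = 1e-8, sigma_d = 1)
  expect_equal(peclet_field(5e-4, dp1, 1e4), 0)
  expect_error(peclet_field(1e-4, dp, 0), "Ld")

  # phi_V at Pe = 0 reduces to diffusive exchange (factor -> 1)
  dpv <- drug_params(Ld = 1e-8, sigma_d = 0.1, c_p = 0)
  expect_equal(vascular_exchange(C = 0.2, c_p = 0, Pe = 0, dpv,
                                 SV = 1e4, J_V = 0),
               -1e-8 * 1e4 * 0.2, tolerance = 1e-10)
  expect_equal(vascular_exchange(C = 0, c_p = 0, Pe = 0.3, dpv,
                                 SV = 1e4, J_V = 1e-4), 0)
  # arithmetic oracle at Pe = 1: Ld*SV*(0 - 0.1) * 1/(e - 1)
  expect_equal(vascular_exchange(C = 0.1, c_p = 0, Pe = 1, dpv,
                                 SV = 1e4, J_V = 0),
               -1e-4 * 0.1 / (exp(1) - 1), tolerance = 1e-12)
  expect_equal(-1e-4 * 0.1 / (exp(1) - 1), -5.820e-6, tolerance = 1e-3)
  # continuity across the removable singularity
  lo <- vascular_exchange(0.1, 0, -1e-8, dpv, 1e4, 0)
  hi <- vascular_exchange(0.1, 0, 1e-8, dpv, 1e4, 0)
  expect_equal(lo, hi, tolerance = 1e-6)

  expect_equal(lymphatic_uptake(0, 1e-4), 0)
  expect_equal(lymphatic_uptake(0.17, 0), 0)
  expect_equal(lymphatic_uptake(0.17, 1e-4), 1.7e-5)
  expect_error(lymphatic_uptake(0.1, -1), "J_L")
})

test_that("initial condition is zero except at the boundary node", {
  pr <- k_profile("homogeneous", K_tumor = 8.8e-15)
  flow <- solve_steady_ifp(grid, pr, geo, par)
  dg <- simulate_drug(flow, drug_params(duration = 60, dt = 10))
  C0 <- dg$C[1, ]
  expect_equal(sum(C0 > 0), 1)
  expect_equal(C0[dg$edge_index], 0.17)
  expect_equal(dg$times[1], 0)
  # the pinned node stays at the bath concentration at all times
  expect_true(all(abs(dg$C[, dg$edge_index] - 0.17) < 1e-12))
})

test_that("pure diffusion matches the half-space erfc solution", {
  # zero all sources and flow (Lp = 0 kills filtration, Ld = 0 kills the
  # transvascular drug sink); uniform Deff via a flat K profile
  par0 <- transport_params(Lp = 0, Lp_normal = 0, LpL = 0)
  K <- 8.8e-15
  pr <- k_profile("homogeneous", K_tumor = K, K_normal = K)
  g <- radial_grid(geo, 800)
  flow <- solve_steady_ifp(g, pr, geo, par0)
  dp <- drug_params(Ld = 0, duration = 30, dt = 0.25, K_ref = K,
                    Deff_ref = 3e-10)
  dg <- simulate_drug(flow, dp, save_every = 1000)
  Cfin <- dg$C[nrow(dg$C), ]
  r_edge <- dg$r[dg$edge_index]
  x <- r_edge - dg$r            # inward depth from the boundary node
  inward <- x >= 0 & x < 8e-4
  ref <- 0.17 * erfc(x[inward] / (2 * sqrt(3e-10 * 30)))
  expect_lt(max(abs(Cfin[inward] - ref)), 0.02 * 0.17)
})

test_that("concentrations obey the maximum principle and mass budget", {
  for (K in c(9.4e-16, 1.6e-14)) {
    flow <- solve_steady_ifp(grid, k_profile("homogeneous", K_tumor = K),
                             geo, par)
    dg <- simulate_drug(flow, drug_params(duration = 1800, dt = 20))
    expect_gte(min(dg$C), 0)
    expect_lte(max(dg$C), 0.17 * (1 + 1e-9))
    expect_lt(dg$budget_residual, 1e-6)
  }
})

test_that("penetration depth increases across the measured K range", {
  depths <- vapply(c(9.4e-16, 8.8e-15, 1.6e-14), function(K) {
    flow <- solve_steady_ifp(grid, k_profile("homogeneous", K_tumor = K),
                             geo, par)
    simulate_drug(flow, drug_params())$penetration_depth
  }, numeric(1))
  expect_true(all(diff(depths) > 0))
  # limited penetration: well under a millimeter-scale fraction of R_t
  expect_true(all(depths < 0.5 * geo$R_t))
  expect_true(all(depths > 0))
})

test_that("penetration threshold is configurable", {
  flow <- solve_steady_ifp(grid, k_profile("homogeneous",
                                           K_tumor = 8.8e-15), geo, par)
  dg <- simulate_drug(flow, drug_params())
  expect_equal(penetration_depth(dg), dg$penetration_depth)
  expect_gte(penetration_depth(dg, frac = 0.001),
             penetration_depth(dg, frac = 0.05))
})
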