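geo <- tumor_geometry()
grid400 <- radial_grid(geo, 400)

test_that("grid resolves every region or refuses", {
  g <- radial_grid(geo, 400)
  expect_equal(length(g$r_centers), 400)
  expect_equal(g$r_faces[1], 0)
  expect_equal(g$r_faces[length(g$r_faces)], geo$R_domain)
  expect_equal(sum(g$V_cells), 4 / 3 * pi * geo$R_domain^3,
               tolerance = 1e-12)
  expect_error(radial_grid(geo, 12), ">= 5 cells")
})

test_that("no vascular source gives identically zero pressure and flow", {
  par0 <- transport_params(Lp = 0, Lp_normal = 0, LpL = 0)
  pr <- k_profile("homogeneous", K_tumor = 1e-14)
  sol <- solve_steady_ifp(grid400, pr, geo, par0)
  expect_equal(max(abs(sol$p_i)), 0)
  expect_equal(max(abs(sol$u_faces)), 0)
  expect_equal(mass_balance_residual(sol)$global, 0)
})

test_that("solution matches the analytic spherical profile", {
  par <- uniform_params()
  K <- 1e-13
  pr <- k_profile("homogeneous", K_tumor = K, K_normal = K)
  p_e <- effective_pressure(par)
  sol <- solve_steady_ifp(grid400, pr, geo, par)
  ref <- ifp_analytic(sol$r, geo$R_domain, K, par$Lp * par$SV, p_e)
  err400 <- sqrt(sum((sol$p_i - ref)^2) / sum(ref^2))
  expect_lt(err400, 0.01)

  # second-order convergence under refinement
  g800 <- radial_grid(geo, 800)
  sol800 <- solve_steady_ifp(g800, pr, geo, par)
  ref800 <- ifp_analytic(sol800$r, geo$R_domain, K, par$Lp * par$SV, p_e)
  err800 <- sqrt(sum((sol800$p_i - ref800)^2) / sum(ref800^2))
  expect_gt(err400 / err800, 3)
  expect_lt(err400 / err800, 5)

  # steep-exchange limit: central plateau approaches p_e
  solsteep <- solve_steady_ifp(grid400,
                               k_profile("homogeneous", K_tumor = 1e-15,
                                         K_normal = 1e-15), geo, par)
  expect_equal(solsteep$p_i[1], p_e, tolerance = 1e-6)
})

test_that("pressure is bounded by the effective filtration pressure", {
  par <- transport_params()
  p_e <- effective_pressure(par)
  for (K in c(9.4e-16, 8.8e-15, 1.6e-14)) {
    sol <- solve_steady_ifp(grid400,
                            k_profile("homogeneous", K_tumor = K),
                            geo, par)
    expect_lte(max(sol$p_i), p_e + 1e-9)
    # IFP non-increasing in r inside the tumor
    in_t <- sol$r <= geo$R_t
    expect_true(all(diff(sol$p_i[in_t]) <= 1e-9 * p_e))
    # boundary conditions
    expect_equal(sol$u_faces[1], 0)
    # near the grounded outer boundary p relaxes to the low normal-tissue
    # baseline (vascular/lymphatic balance), far below tumor pressure
    expect_lt(abs(sol$p_i[length(sol$p_i)]), 0.1 * p_e)
  }
})

test_that("K ordering controls edge pressure, velocity and flow extent", {
  par <- transport_params()
  Ks <- c(9.4e-16, 8.8e-15, 1.6e-14)
  sols <- lapply(Ks, function(K) {
    solve_steady_ifp(grid400, k_profile("homogeneous", K_tumor = K),
                     geo, par)
  })
  edge_ifp <- vapply(sols, function(s) {
    s$p_i[which.min(abs(s$r - geo$R_t))]
  }, numeric(1))
  expect_true(all(diff(edge_ifp) < 0))   # lower K -> higher edge IFP
  max_ifv <- vapply(sols, function(s) max(abs(s$u_faces)), numeric(1))
  expect_true(all(diff(max_ifv) > 0))    # higher K -> higher IFV
  # peak velocity sits at/near the tumor edge
  for (s in sols) {
    r_pk <- s$r_faces[which.max(abs(s$u_faces))]
    expect_lt(abs(r_pk - geo$R_t), 5e-4)
  }
})

test_that("discrete mass balance closes globally and per region", {
  par <- transport_params()
  sol <- solve_steady_ifp(grid400, profile_from_slices(8e-15, 2e-15),
                          geo, par)
  mb <- mass_balance_residual(sol)
  expect_lt(mb$global, 1e-8)
  expect_true(all(mb$per_region < 1e-8))
  expect_lt(sol$residual, 1e-8)
})

test_that("solver validates its inputs", {
  par <- transport_params()
  expect_error(transport_params(sigma = 1.5), "reflection")
  expect_error(transport_params(Lp = -1), ">= 0")
  expect_error(solve_steady_ifp(grid400, "no", geo, par))
})
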