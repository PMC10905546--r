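#' Drug transport parameters
#'
#' Constants of the interstitial advection-diffusion-exchange model.
#' Defaults describe a small-molecule chemotherapeutic (cisplatin-like)
#' delivered intraperitoneally: a fixed bath concentration of
#' 0.17 mol/m^3 held at the tumor edge for 60 min, negligible plasma
#' concentration (`c_p = 0`) over that short exposure, and an effective
#' diffusivity tied to the local hydraulic conductivity through
#' \eqn{D_{eff} = D_{eff}^\circ (K/K^\circ)^{1/3}}.
#'
#' `K_ref` is a fixed, study-wide baseline (default 8.8e-15 m^2/Pa.s, the
#' middle of the three measured anchor conductivities) so that runs with
#' different K maps see genuinely different diffusivities.
#'
#' @param Ld Vascular permeability of the drug, m/s.
#' @param sigma_d Solvent-drag reflection coefficient, in \[0, 1\].
#' @param c_p Plasma drug concentration, mol/m^3.
#' @param C_boundary Concentration held at the tumor edge, mol/m^3.
#' @param duration Exposure time in s.
#' @param dt Time step in s (implicit scheme; controls time accuracy,
#'   not stability).
#' @param Deff_ref Baseline effective diffusivity, m^2/s.
#' @param K_ref Baseline hydraulic conductivity, m^2/Pa.s.
#' @param exponent Diffusivity-conductivity power-law exponent.
#' @param threshold_frac Fraction of `C_boundary` defining the
#'   penetration depth (default 0.01).
#' @return An object of class `drug_params`.
#' @export
drug_params <- function(Ld = 5e-7, sigma_d = 0.1, c_p = 0,
                        C_boundary = 0.17, duration = 3600, dt = 10,
                        Deff_ref = 3e-10, K_ref = 8.8e-15,
                        exponent = 1 / 3, threshold_frac = 0.01) {
  if (sigma_d < 0 || sigma_d > 1) {
    stop("'sigma_d' must lie in [0, 1]", call. = FALSE)
  }
  if (duration <= 0 || dt <= 0) {
    stop("'duration' and 'dt' must be > 0", call. = FALSE)
  }
  structure(list(Ld = Ld, sigma_d = sigma_d, c_p = c_p,
                 C_boundary = C_boundary, duration = duration, dt = dt,
                 Deff_ref = Deff_ref, K_ref = K_ref, exponent = exponent,
                 threshold_frac = threshold_frac),
            class = "drug_params")
}

# Peclet factor Pe/(e^Pe - 1) with its removable singularity at Pe = 0
.peclet_factor <- function(Pe) {
  out <- ifelse(abs(Pe) < 1e-10, 1 - Pe / 2, Pe / expm1(Pe))
  out
}

#' Transvascular Peclet number
#'
#' \deqn{Pe = J_V (1 - \sigma_d) / (L_d S/V)}
#' the ratio of convective to diffusive transport across the vessel wall.
#'
#' @param J_V Vascular filtration rate per node, 1/s.
#' @param params A [drug_params()].
#' @param SV Vascular surface area per volume, 1/m (scalar or per node).
#' @return Peclet number per node.
#' @export
peclet_field <- function(J_V, params, SV) {
  stopifnot(inherits(params, "drug_params"))
  if (any(params$Ld * SV <= 0)) {
    stop("'Ld * SV' must be > 0", call. = FALSE)
  }
  J_V * (1 - params$sigma_d) / (params$Ld * SV)
}

#' Transvascular drug exchange rate
#'
#' \deqn{\phi_V = L_d S/V (c_p - C)\,\frac{Pe}{e^{Pe}-1} + J_V (1-\sigma_d) c_p}
#' with the Peclet factor evaluated as 1 in the limit Pe -> 0.
#'
#' @param C Interstitial concentration per node, mol/m^3.
#' @param c_p Plasma concentration, mol/m^3.
#' @param Pe Peclet number per node.
#' @param params A [drug_params()].
#' @param SV Vascular surface per volume, 1/m.
#' @param J_V Filtration rate per node, 1/s.
#' @return Exchange rate per node, mol/m^3/s (positive into the tissue).
#' @export
vascular_exchange <- function(C, c_p, Pe, params, SV, J_V) {
  stopifnot(inherits(params, "drug_params"))
  params$Ld * SV * (c_p - C) * .peclet_factor(Pe) +
    J_V * (1 - params$sigma_d) * c_p
}

#' Lymphatic drug uptake rate
#'
#' \deqn{\phi_L = J_L C}
#'
#' @param C Interstitial concentration, mol/m^3.
#' @param J_L Lymphatic drainage rate, 1/s (>= 0).
#' @return Uptake rate, mol/m^3/s.
#' @export
lymphatic_uptake <- function(C, J_L) {
  if (any(J_L < 0)) stop("'J_L' must be >= 0", call. = FALSE)
  J_L * C
}

#' Transient interstitial drug concentration
#'
#' Integrates
#' \deqn{\partial C/\partial t = \nabla\cdot(D_{eff}\nabla C)
#'   - \nabla\cdot(u_i C) + \phi_V - \phi_L}
#' on the solved flow field, with a Dirichlet condition
#' `C = C_boundary` at the cell nearest the tumor edge, `C = 0` at the
#' domain boundary, and `C = 0` initially elsewhere. The conservative
#' finite-volume scheme uses harmonic-mean face diffusivities, first-order
#' upwinding of the advective flux, and backward-Euler time stepping (an
#' M-matrix, so concentrations remain nonnegative and bounded without a
#' CFL restriction; `dt` only controls time accuracy). The diffusion term
#' is implemented in conservative form so spatially varying
#' \eqn{D_{eff}(r)} (from the local K via the power law) is handled
#' exactly at cell faces.
#'
#' @param flow A [solve_steady_ifp()] solution (supplies the grid,
#'   geometry, K field, velocities and exchange rates).
#' @param params A [drug_params()].
#' @param save_every Store every `save_every`-th time level (default 10;
#'   the initial and final levels are always stored).
#' @return An object of class `concentration_field`: `times` (s), `C`
#'   (matrix, one row per stored time, one column per cell), `r`,
#'   `penetration_depth` (m, inward from the tumor-edge cell at the final
#'   time, at threshold `threshold_frac * C_boundary`), `edge_index`,
#'   `budget_residual` (relative closure defect of the discrete drug mass
#'   budget), `Deff` (per cell) and the inputs.
#' @export
simulate_drug <- function(flow, params, save_every = 10) {
  stopifnot(inherits(flow, "radial_solution"),
            inherits(params, "drug_params"))
  g <- flow$grid
  n <- g$n_cells
  dr <- g$dr
  V <- g$V_cells
  A <- g$A_faces
  u <- flow$u_faces

  scal <- diffusivity_scaling(params$K_ref, params$Deff_ref,
                              params$exponent)
  Deff <- effective_diffusivity_from_K(flow$K, scal)

  # diffusive face conductances [m^3/s]
  Gd_int <- A[2:n] / (dr / (2 * Deff[1:(n - 1)]) + dr / (2 * Deff[2:n]))
  Gd_out <- A[n + 1] / (dr / (2 * Deff[n]))

  # linear reaction terms: dC/dt += a - b * C
  is_normal <- flow$region == "normal"
  SV_cell <- ifelse(is_normal, flow$params$SV_normal, flow$params$SV) *
    as.numeric(flow$params$vascular_on[as.character(flow$region)])
  vasc <- SV_cell > 0 & params$Ld > 0
  Pe <- numeric(n)
  Pe[vasc] <- peclet_field(flow$J_V[vasc], params, SV_cell[vasc])
  b_v <- numeric(n)
  b_v[vasc] <- params$Ld * SV_cell[vasc] * .peclet_factor(Pe[vasc])
  a_v <- b_v * params$c_p +
    flow$J_V * (1 - params$sigma_d) * params$c_p * as.numeric(vasc)
  b_l <- pmax(flow$J_L, 0)
  a_cell <- a_v
  b_cell <- b_v + b_l

  # assemble dC/dt = L C + a  (rows divided by V)
  lower <- numeric(n - 1)   # coupling of cell i to cell i-1 (face i)
  upper <- numeric(n - 1)   # coupling of cell i to cell i+1 (face i+1)
  diagm <- -b_cell
  u_int <- u[2:n]
  adv_lo <- pmax(u_int, 0) * A[2:n]    # outward flow, upwind = lower cell
  adv_hi <- pmin(u_int, 0) * A[2:n]    # inward flow,  upwind = upper cell
  # face j (between cells j, j+1): flux = Gd*(C_j - C_j1) + adv_lo*C_j + adv_hi*C_j1
  for_j <- seq_len(n - 1)
  # cell j loses flux through face j+1; cell j+1 gains it
  diagm[for_j] <- diagm[for_j] - (Gd_int + adv_lo) / V[for_j]
  upper[for_j] <- (Gd_int - adv_hi) / V[for_j]
  lower[for_j] <- (Gd_int + adv_lo) / V[for_j + 1]
  diagm[for_j + 1] <- diagm[for_j + 1] - (Gd_int - adv_hi) / V[for_j + 1]
  # outer boundary: C = 0 beyond face n+1; advective outflow upwinded
  diagm[n] <- diagm[n] - (Gd_out + max(u[n + 1], 0) * A[n + 1]) / V[n]

  i_edge <- which.min(abs(g$r_centers - flow$geometry$R_t))
  dt <- params$dt
  nt <- ceiling(params$duration / dt)
  dt <- params$duration / nt

  M <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(-dt * lower, 1 - dt * diagm,
                                           -dt * upper))
  M[i_edge, ] <- 0
  M[i_edge, i_edge] <- 1

  C <- numeric(n)
  C[i_edge] <- params$C_boundary
  keep <- unique(c(0, which(seq_len(nt) %% save_every == 0), nt))
  snaps <- matrix(NA_real_, nrow = length(keep), ncol = n)
  times <- keep * dt
  snaps[1, ] <- C
  ksnap <- 2L

  Mfac <- Matrix::lu(M)
  influx_tot <- 0
  defect_tot <- 0
  others <- setdiff(seq_len(n), i_edge)
  for (m in seq_len(nt)) {
    rhs <- C + dt * a_cell
    rhs[i_edge] <- params$C_boundary
    Cn <- as.numeric(Matrix::solve(Mfac, rhs))
    if (min(Cn) < -1e-9 * params$C_boundary) {
      stop("negative concentrations beyond tolerance: min C = ",
           format(min(Cn)), call. = FALSE)
    }
    # independent budget audit from the face-flux formulas at C^{m+1}
    flux_f <- c(0, Gd_int * (Cn[1:(n - 1)] - Cn[2:n]) +
                  adv_lo * Cn[1:(n - 1)] + adv_hi * Cn[2:n],
                Gd_out * Cn[n] + max(u[n + 1], 0) * A[n + 1] * Cn[n])
    infl_edge <- flux_f[i_edge + 1] - flux_f[i_edge]  # out of pinned cell
    out_dom <- if (i_edge == n) 0 else flux_f[n + 1]
    clear <- sum(V[others] * (b_cell[others] * Cn[others] -
                                a_cell[others]))
    dmass <- sum(V[others] * (Cn[others] - C[others]))
    defect_tot <- defect_tot +
      abs(dmass - dt * (infl_edge - out_dom - clear))
    influx_tot <- influx_tot + dt * abs(infl_edge)
    C <- Cn
    if (ksnap <= length(keep) && m == keep[ksnap]) {
      snaps[ksnap, ] <- C
      ksnap <- ksnap + 1L
    }
  }

  r_edge <- g$r_centers[i_edge]
  thr <- params$threshold_frac * params$C_boundary
  inside <- which(g$r_centers < r_edge & C >= thr)
  depth <- if (length(inside)) r_edge - min(g$r_centers[inside]) else 0
  structure(list(times = times, C = snaps, r = g$r_centers,
                 penetration_depth = depth, edge_index = i_edge,
                 budget_residual = defect_tot /
                   max(influx_tot, .Machine$double.xmin),
                 Deff = Deff, Pe = Pe, flow = flow, params = params),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat("<concentration_field>", length(x$r), "cells,",
      length(x$times), "stored times to", max(x$times), "s\n")
  cat(sprintf("  penetration depth %.3g mm (threshold %.3g mol/m^3)\n",
              1e3 * x$penetration_depth,
              x$params$threshold_frac * x$params$C_boundary))
  cat(sprintf("  budget defect %.3g\n", x$budget_residual))
  invisible(x)
}

#' Penetration depth of a simulated concentration field
#'
#' Largest distance inward from the tumor-edge cell at which the final
#' concentration exceeds `frac * C_boundary`.
#'
#' @param field A [simulate_drug()] result.
#' @param frac Threshold fraction; defaults to the fraction stored in the
#'   field's parameters.
#' @return Depth in m.
#' @export
penetration_depth <- function(field, frac = NULL) {
  stopifnot(inherits(field, "concentration_field"))
  if (is.null(frac)) frac <- field$params$threshold_frac
  Cfin <- field$C[nrow(field$C), ]
  r_edge <- field$r[field$edge_index]
  thr <- frac * field$params$C_boundary
  inside <- which(field$r < r_edge & Cfin >= thr)
  if (length(inside)) r_edge - min(field$r[inside]) else 0
}
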