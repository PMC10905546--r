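#' Uniform radial finite-volume grid
#'
#' Cells are spherical shells with faces from r = 0 to `R_domain`;
#' unknowns live at cell centers. The grid must resolve every region of
#' nonzero width with at least 5 cells.
#'
#' @param geometry A [tumor_geometry()].
#' @param n_cells Number of cells (default 800).
#' @return An object of class `radial_grid` with `r_faces` (length
#'   `n_cells + 1`), `r_centers`, `dr`, `n_cells`, face areas `A_faces`
#'   and cell volumes `V_cells`.
#' @export
radial_grid <- function(geometry, n_cells = 800) {
  stopifnot(inherits(geometry, "tumor_geometry"), n_cells >= 10)
  r_f <- seq(0, geometry$R_domain, length.out = n_cells + 1)
  dr <- r_f[2] - r_f[1]
  r_c <- (r_f[-1] + r_f[-length(r_f)]) / 2
  breaks <- c(0, geometry$R_n, geometry$R_hypoxic, geometry$R_t,
              geometry$R_domain)
  widths <- diff(breaks)
  counts <- vapply(seq_len(4), function(i) {
    sum(r_c > breaks[i] & r_c <= breaks[i + 1])
  }, integer(1))
  if (any(widths > 0 & counts < 5)) {
    stop("grid does not resolve every region with >= 5 cells; ",
         "increase n_cells", call. = FALSE)
  }
  structure(list(r_faces = r_f, r_centers = r_c, dr = dr,
                 n_cells = n_cells,
                 A_faces = 4 * pi * r_f^2,
                 V_cells = 4 / 3 * pi * diff(r_f^3)),
            class = "radial_grid")
}

#' Vascular and lymphatic transport parameters
#'
#' Starling-exchange and lymphatic-drainage constants for tumor and
#' normal tissue. Defaults are literature values in the classic range for
#' solid-tumor interstitial flow models; with them the tumor effective
#' filtration pressure is
#' \eqn{p_e = p_v - \sigma(\pi_v - \pi_i) \approx 1.53} kPa,
#' which caps the achievable interstitial pressure.
#'
#' Regional switches control where the vascular source and the lymphatic
#' sink act: by default vasculature is off in the necrotic core and on
#' elsewhere, and lymphatics operate only in normal tissue.
#'
#' @param Lp Tumor vascular hydraulic conductivity, m/Pa.s.
#' @param SV Tumor vascular surface area per volume, 1/m.
#' @param p_v Vascular pressure, Pa.
#' @param sigma Tumor osmotic reflection coefficient, in \[0, 1\].
#' @param pi_v Vascular osmotic pressure, Pa.
#' @param pi_i Tumor interstitial osmotic pressure, Pa.
#' @param Lp_normal,SV_normal,sigma_normal,pi_i_normal Normal-tissue
#'   counterparts (vascular pressure and plasma osmotic pressure are
#'   shared).
#' @param LpL Lymphatic wall conductivity, m/Pa.s.
#' @param SLVL Lymphatic surface area per volume, 1/m.
#' @param p_L Effective lymphatic pressure, Pa.
#' @param vascular_on Named logical vector over
#'   `c(necrotic, hypoxic, viable, normal)`.
#' @param lymphatic_on Same shape; sink active where `TRUE`.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(Lp = 2.1e-11, SV = 2e4,
                             p_v = 2080, sigma = 0.82,
                             pi_v = 2666, pi_i = 2000,
                             Lp_normal = 2.7e-12, SV_normal = 7000,
                             sigma_normal = 0.91, pi_i_normal = 1330,
                             LpL = 1.33e-11, SLVL = 1e4, p_L = 0,
                             vascular_on = c(necrotic = FALSE,
                                             hypoxic = TRUE,
                                             viable = TRUE,
                                             normal = TRUE),
                             lymphatic_on = c(necrotic = FALSE,
                                              hypoxic = FALSE,
                                              viable = FALSE,
                                              normal = TRUE)) {
  if (Lp < 0 || SV < 0 || Lp_normal < 0 || SV_normal < 0 ||
      LpL < 0 || SLVL < 0) {
    stop("conductivities and surface densities must be >= 0", call. = FALSE)
  }
  if (sigma < 0 || sigma > 1 || sigma_normal < 0 || sigma_normal > 1) {
    stop("reflection coefficients must lie in [0, 1]", call. = FALSE)
  }
  vascular_on <- unlist(vascular_on)
  lymphatic_on <- unlist(lymphatic_on)
  regions <- c("necrotic", "hypoxic", "viable", "normal")
  if (!all(regions %in% names(vascular_on)) ||
      !all(regions %in% names(lymphatic_on))) {
    stop("region switches need entries for: ",
         paste(regions, collapse = ", "), call. = FALSE)
  }
  structure(list(Lp = Lp, SV = SV, p_v = p_v, sigma = sigma,
                 pi_v = pi_v, pi_i = pi_i,
                 Lp_normal = Lp_normal, SV_normal = SV_normal,
                 sigma_normal = sigma_normal, pi_i_normal = pi_i_normal,
                 LpL = LpL, SLVL = SLVL, p_L = p_L,
                 vascular_on = vascular_on[regions],
                 lymphatic_on = lymphatic_on[regions]),
            class = "transport_params")
}

#' Effective filtration pressure
#'
#' \eqn{p_e = p_v - \sigma(\pi_v - \pi_i)} for tumor (`tissue = "tumor"`)
#' or normal tissue parameters.
#'
#' @param params A [transport_params()].
#' @param tissue `"tumor"` or `"normal"`.
#' @return Effective pressure in Pa.
#' @export
effective_pressure <- function(params, tissue = c("tumor", "normal")) {
  tissue <- match.arg(tissue)
  if (tissue == "tumor") {
    params$p_v - params$sigma * (params$pi_v - params$pi_i)
  } else {
    params$p_v - params$sigma_normal * (params$pi_v - params$pi_i_normal)
  }
}

# per-cell source coefficients: J_V = LpSV * (p_e - p), J_L = LL * (p - p_L)
.cell_coefficients <- function(region, params) {
  is_normal <- region == "normal"
  LpSV <- ifelse(is_normal, params$Lp_normal * params$SV_normal,
                 params$Lp * params$SV)
  LpSV <- LpSV * as.numeric(params$vascular_on[as.character(region)])
  p_e <- ifelse(is_normal, effective_pressure(params, "normal"),
                effective_pressure(params, "tumor"))
  LL <- params$LpL * params$SLVL *
    as.numeric(params$lymphatic_on[as.character(region)])
  list(LpSV = LpSV, p_e = p_e, LL = LL)
}

#' Steady interstitial fluid pressure and velocity
#'
#' Solves the spherically symmetric Darcy/continuity balance
#' \deqn{-\nabla\cdot(K \nabla p_i) = J_V(p_i) - J_L(p_i)}
#' with Starling transvascular inflow
#' \eqn{J_V = L_p S/V (p_v - p_i - \sigma(\pi_v - \pi_i))} and lymphatic
#' drainage \eqn{J_L = L_{pL} S_L/V_L (p_i - p_L)}, by a conservative
#' finite-volume discretization: harmonic averaging of K at cell faces
#' (exact flux continuity across conductivity jumps), a zero-flux symmetry
#' condition at r = 0, and a Dirichlet condition p = 0 at the outer face.
#' Since both exchange terms are linear in p, the discrete system is a
#' single sparse tridiagonal solve.
#'
#' @param grid A [radial_grid()].
#' @param profile A [k_profile()].
#' @param geometry A [tumor_geometry()].
#' @param params A [transport_params()].
#' @return An object of class `radial_solution`: `r` (cell centers),
#'   `p_i` (Pa), `u_faces` (m/s at the `n_cells + 1` faces, `u_faces[1] = 0`),
#'   `r_faces`, `J_V`, `J_L` (1/s per cell), `region`, `K` (per cell),
#'   `residual` (global mass-balance defect) plus the inputs.
#' @export
solve_steady_ifp <- function(grid, profile, geometry, params) {
  stopifnot(inherits(grid, "radial_grid"), inherits(profile, "k_profile"),
            inherits(geometry, "tumor_geometry"),
            inherits(params, "transport_params"))
  n <- grid$n_cells
  r_c <- grid$r_centers
  dr <- grid$dr
  K_c <- evaluate_K(profile, geometry, r_c)
  region <- region_of(geometry, r_c)
  cf <- .cell_coefficients(region, params)

  # face conductances G [m^3/Pa.s]: interior faces 2..n between cells i-1, i
  A_int <- grid$A_faces[2:n]
  G_int <- A_int / (dr / (2 * K_c[1:(n - 1)]) + dr / (2 * K_c[2:n]))
  A_out <- grid$A_faces[n + 1]
  G_out <- A_out / (dr / (2 * K_c[n]))      # Dirichlet p = 0 at outer face

  V <- grid$V_cells
  diag_main <- V * (cf$LpSV + cf$LL)
  diag_main[1] <- diag_main[1] + G_int[1]
  if (n > 2) {
    diag_main[2:(n - 1)] <- diag_main[2:(n - 1)] +
      G_int[1:(n - 2)] + G_int[2:(n - 1)]
  }
  diag_main[n] <- diag_main[n] + G_int[n - 1] + G_out
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(-G_int, diag_main, -G_int))
  b <- V * (cf$LpSV * cf$p_e + cf$LL * params$p_L)
  p <- as.numeric(Matrix::solve(A, b))
  if (any(!is.finite(p))) {
    stop("IFP solve failed: non-finite pressures (singular system?); ",
         "check K profile and exchange coefficients", call. = FALSE)
  }

  u_faces <- numeric(n + 1)
  u_faces[2:n] <- G_int * (p[1:(n - 1)] - p[2:n]) / A_int
  u_faces[n + 1] <- G_out * p[n] / A_out
  J_V <- cf$LpSV * (cf$p_e - p)
  J_L <- cf$LL * (p - params$p_L)

  net_src <- sum(V * (J_V - J_L))
  defect <- abs(u_faces[n + 1] * A_out - net_src)
  scale <- max(sum(V * abs(J_V)), .Machine$double.xmin)
  structure(list(r = r_c, p_i = p, u_faces = u_faces,
                 r_faces = grid$r_faces,
                 J_V = J_V, J_L = J_L, region = region, K = K_c,
                 p_e = cf$p_e, residual = defect / scale,
                 grid = grid, geometry = geometry, profile = profile,
                 params = params),
            class = "radial_solution")
}

#' @export
print.radial_solution <- function(x, ...) {
  cat("<radial_solution>", x$grid$n_cells, "cells to",
      format(x$geometry$R_domain), "m\n")
  cat(sprintf("  max IFP    %.4g Pa (at r = %.3g m)\n",
              max(x$p_i), x$r[which.max(x$p_i)]))
  cat(sprintf("  max |IFV|  %.4g m/s\n", max(abs(x$u_faces))))
  cat(sprintf("  mass-balance defect %.3g\n", x$residual))
  invisible(x)
}

#' Mass-balance audit of a solved flow field
#'
#' Conservation check of the discrete continuity equation: for the whole
#' domain and per region, the net volumetric outflow through the bounding
#' faces minus the integrated source must vanish. Defects are normalized
#' by the total absolute vascular source.
#'
#' @param solution A [solve_steady_ifp()] result.
#' @return A list with `global` (dimensionless defect) and `per_region`
#'   (named numeric vector over the regions present).
#' @export
mass_balance_residual <- function(solution) {
  stopifnot(inherits(solution, "radial_solution"))
  g <- solution$grid
  V <- g$V_cells
  flux <- solution$u_faces * g$A_faces    # volumetric flow through faces
  src <- V * (solution$J_V - solution$J_L)
  scale <- max(sum(V * abs(solution$J_V)), .Machine$double.xmin)
  per <- vapply(levels(solution$region), function(reg) {
    idx <- which(solution$region == reg)
    if (!length(idx)) return(NA_real_)
    out_face <- max(idx) + 1L
    in_face <- min(idx)
    abs((flux[out_face] - flux[in_face]) - sum(src[idx])) / scale
  }, numeric(1))
  list(global = abs(flux[length(flux)] - sum(src)) / scale,
       per_region = per[!is.na(per)])
}
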