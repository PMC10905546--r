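#' Porous-medium description of tumor interstitium
#'
#' @param epsilon Porosity, dimensionless in (0, 1).
#' @param alpha Pore surface area per bulk volume, 1/m.
#' @param Q Kozeny-Carman constant (dimensionless); approximately 5 for
#'   porosities below 0.7.
#' @param mu Interstitial fluid dynamic viscosity, Pa.s.
#' @param D_free Free-fluid diffusion coefficient of the solute, m^2/s.
#' @return An object of class `porous_medium`.
#' @export
porous_medium <- function(epsilon, alpha, Q = 5, mu = 3.5e-3,
                          D_free = 1e-9) {
  if (!(epsilon > 0 && epsilon < 1)) {
    stop("'epsilon' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  if (Q <= 0) stop("'Q' must be > 0", call. = FALSE)
  structure(list(epsilon = epsilon, alpha = alpha, Q = Q, mu = mu,
                 D_free = D_free),
            class = "porous_medium")
}

#' Kozeny-Carman intrinsic permeability
#'
#' \deqn{k = \varepsilon^3 / (Q \alpha^2)}
#'
#' @param medium A [porous_medium()].
#' @return Intrinsic permeability k in m^2.
#' @export
kc_permeability <- function(medium) {
  stopifnot(inherits(medium, "porous_medium"))
  medium$epsilon^3 / (medium$Q * medium$alpha^2)
}

#' Hydraulic conductivity from intrinsic permeability
#'
#' \deqn{K = k / \mu}
#'
#' @param k Intrinsic permeability, m^2.
#' @param mu Interstitial fluid dynamic viscosity, Pa.s.
#' @return Hydraulic conductivity K in m^2/Pa.s.
#' @export
conductivity_from_permeability <- function(k, mu) {
  if (any(mu <= 0)) stop("'mu' must be > 0", call. = FALSE)
  k / mu
}

#' Effective diffusivity from porosity
#'
#' The solid matrix excludes part of the cross-section available to
#' diffusion, so \eqn{D_{eff} = \varepsilon D}.
#'
#' @param epsilon Porosity in \[0, 1\].
#' @param D_free Free-fluid diffusion coefficient, m^2/s.
#' @return Effective diffusivity in m^2/s.
#' @export
effective_diffusivity_porosity <- function(epsilon, D_free) {
  epsilon * D_free
}

#' Baseline scaling linking conductivity and effective diffusivity
#'
#' Holds the reference pair (K_ref, Deff_ref) and the power-law exponent
#' used by [effective_diffusivity_from_K()]. The default exponent 1/3 is
#' the unique value consistent with the porosity relations
#' \eqn{D_{eff} \propto \varepsilon} and \eqn{K \propto \varepsilon^3}.
#'
#' @param K_ref Baseline hydraulic conductivity, m^2/Pa.s.
#' @param Deff_ref Baseline effective diffusivity, m^2/s.
#' @param exponent Power-law exponent (dimensionless).
#' @return An object of class `diffusivity_scaling`.
#' @export
diffusivity_scaling <- function(K_ref, Deff_ref, exponent = 1 / 3) {
  if (K_ref <= 0 || Deff_ref <= 0) {
    stop("'K_ref' and 'Deff_ref' must be > 0", call. = FALSE)
  }
  structure(list(K_ref = K_ref, Deff_ref = Deff_ref, exponent = exponent),
            class = "diffusivity_scaling")
}

#' Effective diffusivity scaled from local hydraulic conductivity
#'
#' \deqn{D_{eff} = D_{eff}^\circ (K / K^\circ)^{e}}
#' with exponent e = 1/3 by default (see [diffusivity_scaling()]).
#'
#' @param K Local hydraulic conductivity, m^2/Pa.s (vectorized, > 0).
#' @param scaling A [diffusivity_scaling()].
#' @return Effective diffusivity in m^2/s.
#' @export
effective_diffusivity_from_K <- function(K, scaling) {
  stopifnot(inherits(scaling, "diffusivity_scaling"))
  if (any(K <= 0)) stop("'K' must be > 0", call. = FALSE)
  scaling$Deff_ref * (K / scaling$K_ref)^scaling$exponent
}
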