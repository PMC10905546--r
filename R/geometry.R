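#' Three-region spherical tumor geometry
#'
#' The simulated tumor is a sphere of radius `R_t` consisting of a
#' necrotic core (radius `R_n`), a hypoxic shell of given thickness, and a
#' viable rim filling the remainder (which has zero width under the
#' defaults: 5 mm core diameter plus a 2.5 mm hypoxic shell fills the
#' 10 mm tumor). The sphere is embedded in normal tissue out to `R_domain`,
#' where the interstitial pressure is pinned to 0 Pa.
#'
#' @param R_t Tumor radius in m (default 5e-3).
#' @param R_n Necrotic-core radius in m (default 2.5e-3).
#' @param hypoxic_thickness Thickness of the hypoxic shell in m
#'   (default 2.5e-3).
#' @param R_domain Outer radius of the computational domain in m
#'   (default `4 * R_t`).
#' @return An object of class `tumor_geometry`.
#' @export
tumor_geometry <- function(R_t = 5e-3, R_n = 2.5e-3,
                           hypoxic_thickness = 2.5e-3,
                           R_domain = 4 * R_t) {
  if (!(R_n > 0 && R_n + hypoxic_thickness <= R_t && R_t < R_domain)) {
    stop("require 0 < R_n, R_n + hypoxic_thickness <= R_t < R_domain",
         call. = FALSE)
  }
  structure(list(R_t = R_t, R_n = R_n,
                 hypoxic_thickness = hypoxic_thickness,
                 R_hypoxic = R_n + hypoxic_thickness,
                 R_domain = R_domain),
            class = "tumor_geometry")
}

#' Region classification of radii
#'
#' @param geometry A [tumor_geometry()].
#' @param r Radii in m.
#' @return Factor with levels `necrotic`, `hypoxic`, `viable`, `normal`.
#' @export
region_of <- function(geometry, r) {
  stopifnot(inherits(geometry, "tumor_geometry"))
  reg <- ifelse(r <= geometry$R_n, "necrotic",
         ifelse(r <= geometry$R_hypoxic, "hypoxic",
         ifelse(r <= geometry$R_t, "viable", "normal")))
  factor(reg, levels = c("necrotic", "hypoxic", "viable", "normal"))
}

#' Radial hydraulic-conductivity profile
#'
#' Two shapes are supported. `"homogeneous"`: a single tumor value
#' `K_tumor` inside `R_t`, ramping smoothly to `K_normal` over
#' `transition_width`. `"heterogeneous"`: a constant `K_necrotic` in the
#' core, a monotone smooth rise from `K2` at the core boundary to `K1` at
#' the tumor edge, then the same ramp to `K_normal`. All interpolation is
#' done in log10(K) with a cubic smoothstep, which keeps the profile
#' positive, monotone between anchors and continuously differentiable at
#' the region boundaries.
#'
#' @param shape `"homogeneous"` or `"heterogeneous"`.
#' @param K_tumor Tumor conductivity for the homogeneous shape, m^2/Pa.s.
#' @param K1 Edge conductivity (at `R_t`) for the heterogeneous shape.
#' @param K2 Interior conductivity (at `R_n`) for the heterogeneous shape.
#' @param K_necrotic Core conductivity; defaults to `K2`.
#' @param K_normal Normal-tissue conductivity; defaults to 5x the value at
#'   the tumor edge, the contrast used in the simulations.
#' @param transition_width Width of the tumor/normal ramp in m
#'   (default 5e-4).
#' @return An object of class `k_profile`.
#' @export
k_profile <- function(shape = c("homogeneous", "heterogeneous"),
                      K_tumor = NULL, K1 = NULL, K2 = NULL,
                      K_necrotic = NULL, K_normal = NULL,
                      transition_width = 5e-4) {
  shape <- match.arg(shape)
  if (shape == "homogeneous") {
    if (is.null(K_tumor) || K_tumor <= 0) {
      stop("homogeneous profile needs K_tumor > 0", call. = FALSE)
    }
    K1 <- K2 <- K_necrotic <- K_tumor
  } else {
    if (is.null(K1) || is.null(K2) || K1 <= 0 || K2 <= 0) {
      stop("heterogeneous profile needs K1 > 0 and K2 > 0", call. = FALSE)
    }
    if (is.null(K_necrotic)) K_necrotic <- K2
  }
  if (is.null(K_normal)) K_normal <- 5 * K1
  if (K_necrotic <= 0 || K_normal <= 0) {
    stop("all K values must be > 0", call. = FALSE)
  }
  if (transition_width <= 0) {
    stop("'transition_width' must be > 0", call. = FALSE)
  }
  structure(list(shape = shape, K1 = K1, K2 = K2,
                 K_necrotic = K_necrotic, K_normal = K_normal,
                 transition_width = transition_width),
            class = "k_profile")
}

#' @export
print.k_profile <- function(x, ...) {
  cat("<k_profile>", x$shape, "\n")
  cat(sprintf("  K1 (edge)    %.3g\n  K2 (core bd) %.3g\n", x$K1, x$K2))
  cat(sprintf("  K_necrotic   %.3g\n  K_normal     %.3g m^2/Pa.s\n",
              x$K_necrotic, x$K_normal))
  cat(sprintf("  transition   %.3g m\n", x$transition_width))
  invisible(x)
}

#' Build a K profile from two measured slices
#'
#' The most superficial slice (S1) of a specimen samples the tumor edge
#' and a deeper slice (S2) the interior, so their measured conductivities
#' anchor the heterogeneous radial map: `K1 = K_S1` at the tumor surface,
#' `K2 = K_S2` at the necrotic boundary, with the core held at `K_S2`.
#' Normal tissue is assigned `K_normal_factor` times the edge value.
#'
#' @param K_S1 Conductivity of the superficial slice, m^2/Pa.s.
#' @param K_S2 Conductivity of the deeper slice, m^2/Pa.s.
#' @param K_normal_factor Tumor-edge-to-normal contrast (default 5).
#' @param transition_width Ramp width in m.
#' @return A heterogeneous [k_profile()] (degenerating to a flat
#'   intratumoral map when `K_S1 == K_S2`).
#' @export
profile_from_slices <- function(K_S1, K_S2, K_normal_factor = 5,
                                transition_width = 5e-4) {
  stopifnot(K_S1 > 0, K_S2 > 0, K_normal_factor > 0)
  k_profile("heterogeneous", K1 = K_S1, K2 = K_S2, K_necrotic = K_S2,
            K_normal = K_normal_factor * K_S1,
            transition_width = transition_width)
}

# cubic smoothstep on [0,1]; C1, monotone
.smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# log-space blend between two positive values as t goes 0 -> 1
.log_blend <- function(Ka, Kb, t) {
  10^(log10(Ka) + (log10(Kb) - log10(Ka)) * .smoothstep(t))
}

#' Evaluate a K profile at given radii
#'
#' @param profile A [k_profile()].
#' @param geometry A [tumor_geometry()].
#' @param r Radii in m, each in `[0, R_domain]`.
#' @return Hydraulic conductivity K(r) in m^2/Pa.s (vectorized).
#' @export
evaluate_K <- function(profile, geometry, r) {
  stopifnot(inherits(profile, "k_profile"),
            inherits(geometry, "tumor_geometry"))
  if (any(r < 0 | r > geometry$R_domain)) {
    stop("radius outside [0, R_domain]", call. = FALSE)
  }
  R_n <- geometry$R_n; R_t <- geometry$R_t
  tw <- profile$transition_width
  K <- numeric(length(r))
  if (profile$shape == "homogeneous") {
    inner <- r <= R_t
    K[inner] <- profile$K1
    ramp <- !inner
    K[ramp] <- .log_blend(profile$K1, profile$K_normal,
                          (r[ramp] - R_t) / tw)
  } else {
    core <- r <= R_n
    K[core] <- profile$K_necrotic
    mid <- r > R_n & r <= R_t
    K[mid] <- .log_blend(profile$K2, profile$K1,
                         (r[mid] - R_n) / (R_t - R_n))
    out <- r > R_t
    K[out] <- .log_blend(profile$K1, profile$K_normal,
                         (r[out] - R_t) / tw)
  }
  K
}
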