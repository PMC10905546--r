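#' Specification of a synthetic tissue-sample cohort
#'
#' Describes the ground truth of a generated cohort: collagen area
#' density drawn uniformly over `collagen_range`, and
#' `log10(K) = k_intercept + k_collagen_slope * collagen_pct + noise`
#' with lognormal (Gaussian-in-log10) K noise. Cell and fibroblast
#' densities are drawn independently of K, so only the collagen
#' association is planted. Defaults mimic the measured cohort: 29
#' samples, an inverse collagen effect sized so that the expected
#' K-collagen R^2 is
#' `b^2 Var(x) / (b^2 Var(x) + noise_sd^2) = 0.79`,
#' and tumor K values spanning roughly 1e-15 to 1e-14 m^2/Pa.s.
#'
#' @param n_samples Number of samples (>= 3; default 29).
#' @param collagen_range Collagen density range, percent.
#' @param k_collagen_slope Planted slope, log10(K) units per percent
#'   (negative: denser collagen, lower conductivity).
#' @param k_intercept Intercept of the planted log10(K) model.
#' @param noise_sd SD of the log10(K) noise (lognormal K noise).
#' @param cell_range,fibroblast_range Ranges of the independent
#'   densities, percent.
#' @param seed Integer seed; the generator is fully deterministic
#'   given the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 29, collagen_range = c(10, 50),
                        k_collagen_slope = -0.025, k_intercept = -13.85,
                        noise_sd = 0.15,
                        cell_range = c(5, 40), fibroblast_range = c(2, 40),
                        seed = 1L) {
  if (n_samples < 3) stop("'n_samples' must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 collagen_range = collagen_range,
                 k_collagen_slope = k_collagen_slope,
                 k_intercept = k_intercept,
                 noise_sd = noise_sd,
                 cell_range = cell_range,
                 fibroblast_range = fibroblast_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.tumor_types <- c("PC", "PM-CRC", "PM-CRC-AW", "PM-SB", "PM-OC",
                  "OM-SB", "NP")

#' Generate a synthetic tissue-sample cohort
#'
#' Draws a cohort according to a [cohort_spec()]: a planted inverse
#' collagen-conductivity relation on the log10(K) scale, independent cell
#' and fibroblast densities, and tumor-type labels assigned round-robin
#' over the seven study categories (labels are cosmetic; the planted
#' structure does not depend on type).
#'
#' @param spec A [cohort_spec()].
#' @return A cohort data.frame (see [validate_cohort()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  out <- withr_seed(spec$seed, {
    collagen <- stats::runif(n, spec$collagen_range[1],
                             spec$collagen_range[2])
    log10K <- spec$k_intercept + spec$k_collagen_slope * collagen +
      stats::rnorm(n, 0, spec$noise_sd)
    cellp <- stats::runif(n, spec$cell_range[1], spec$cell_range[2])
    fibro <- stats::runif(n, spec$fibroblast_range[1],
                          spec$fibroblast_range[2])
    data.frame(
      sample_id = sprintf("T%dS%d", (seq_len(n) - 1) %/% 2 + 1,
                          (seq_len(n) - 1) %% 2 + 1),
      tumor_type = rep_len(.tumor_types, n),
      K = 10^log10K,
      collagen_pct = collagen,
      cell_pct = cellp,
      fibroblast_pct = fibro,
      stringsAsFactors = FALSE)
  })
  validate_cohort(out)
}

# run expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic bubble track from a known conductivity
#'
#' Inverts the chamber equation: given a true corrected conductivity
#' `K_true`, the implied nominal conductivity at the (sampled) operating
#' temperature is `K' = K_true * mu_IF / mu_PBS(T)` and the bubble drifts
#' at `v = K' rho g h / ((b/d)^2 w)`. Positions are sampled every 600 s
#' for 7200 s (13 frames) with additive Gaussian position noise, so the
#' full analysis chain can be audited against ground truth.
#'
#' @param K_true True corrected conductivity, m^2/Pa.s (> 0).
#' @param chamber Named list of [ussing_measurement()] geometry overrides.
#' @param noise_sd_position SD of the position noise in m (default 5e-6,
#'   i.e. 5 micrometer localization error).
#' @param seed Integer seed.
#' @param temperature_C Operating temperature; `NULL` (default) samples
#'   uniformly in \[18, 25\] degC.
#' @param mu_if Interstitial-fluid viscosity used in the inversion, Pa.s.
#' @return An `ussing_measurement` whose analysis recovers `K_true`
#'   (exactly, for zero noise).
#' @export
generate_bubble_track <- function(K_true, chamber = list(),
                                  noise_sd_position = 5e-6, seed = 1L,
                                  temperature_C = NULL, mu_if = 3.5e-3) {
  stopifnot(K_true > 0)
  withr_seed(seed, {
    if (is.null(temperature_C)) temperature_C <- stats::runif(1, 18, 25)
    defaults <- list(w = 1e-3, d = 5.05e-3, b = 1e-3, rho = 998,
                     h = 0.16, g = 9.81)
    geom <- utils::modifyList(defaults, chamber)
    mu_pbs <- pbs_viscosity(temperature_C)
    K_nom <- K_true * mu_if / mu_pbs
    v <- K_nom * geom$rho * geom$g * geom$h / ((geom$b / geom$d)^2 * geom$w)
    times <- seq(0, 7200, by = 600)
    positions <- v * times +
      if (noise_sd_position > 0) {
        stats::rnorm(length(times), 0, noise_sd_position)
      } else 0
    do.call(ussing_measurement,
            c(list(sample_id = sprintf("synthK%.3g", K_true),
                   times = times, positions = positions,
                   temperature_C = temperature_C),
              geom))
  })
}
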