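#' Ussing-chamber measurement of a tissue slice
#'
#' Bundles one bubble-tracking run with the chamber geometry and fluid
#' constants needed to convert the bubble drift velocity into a hydraulic
#' conductivity. Defaults correspond to the standard bench configuration:
#' a 1 mm thick tissue disc exposed over a 5.05 mm wet diameter, a 1 mm
#' internal-diameter tracking tube, PBS at room temperature, and a 16 cm
#' liquid column (about 1.6 kPa of driving pressure).
#'
#' @param sample_id Character label, e.g. `"T1S1"` (tumor 1, slice 1).
#' @param times Numeric vector of frame times in seconds, strictly
#'   increasing, at least 3 points. A typical run images the bubble every
#'   600 s for 7200 s.
#' @param positions Numeric vector of bubble positions along the tube in
#'   meters, same length as `times`.
#' @param temperature_C Operating room temperature in Celsius. Values
#'   outside `[18, 25]` trigger a warning (the viscosity anchors are
#'   extrapolated).
#' @param w Tissue slice thickness in m.
#' @param d Tissue wet diameter (diameter of the area exposed to fluid) in m.
#' @param b Internal diameter of the bubble-tracking tube in m.
#' @param rho Liquid density in kg/m^3.
#' @param h Liquid column height (pressure head difference) in m.
#' @param g Gravitational acceleration in m/s^2.
#'
#' @return An object of class `ussing_measurement`.
#' @seealso [measure_conductivity()], [generate_bubble_track()]
#' @export
#' @examples
#' m <- ussing_measurement("T1S1", times = c(0, 600, 1200),
#'                         positions = c(0, 6e-5, 1.2e-4))
#' measure_conductivity(m)
ussing_measurement <- function(sample_id, times, positions,
                               temperature_C = 21,
                               w = 1e-3, d = 5.05e-3, b = 1e-3,
                               rho = 998, h = 0.16, g = 9.81) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  times <- as.numeric(times)
  positions <- as.numeric(positions)
  if (length(times) < 3L || length(positions) != length(times)) {
    stop("need at least 3 (time, position) pairs of equal length",
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  geom <- c(w = w, d = d, b = b, rho = rho, h = h, g = g)
  if (any(!is.finite(geom)) || any(geom <= 0)) {
    stop("all geometric and fluid quantities must be strictly positive",
         call. = FALSE)
  }
  if (temperature_C < 18 || temperature_C > 25) {
    warning("temperature ", temperature_C,
            " degC outside the calibrated 18-25 degC range; ",
            "viscosity will be extrapolated", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, times = times, positions = positions,
         temperature_C = temperature_C,
         w = w, d = d, b = b, rho = rho, h = h, g = g),
    class = "ussing_measurement"
  )
}

#' @export
print.ussing_measurement <- function(x, ...) {
  cat("<ussing_measurement> sample", x$sample_id, "\n")
  cat("  frames:", length(x$times), "over",
      diff(range(x$times)), "s at", format(x$temperature_C), "degC\n")
  cat("  geometry: w =", format(x$w), "m, d =", format(x$d),
      "m, b =", format(x$b), "m, head h =", format(x$h), "m\n")
  invisible(x)
}

#' Bubble drift velocity by least squares
#'
#' Estimates the bubble velocity dx/dt as the ordinary least-squares slope
#' of position against time, using every imaged frame rather than only the
#' first/last pair, and returns its standard error as a precision measure.
#'
#' @param times Frame times in seconds, strictly increasing, length >= 3.
#' @param positions Bubble positions in meters.
#' @return A list with elements `velocity` (m/s) and `stderr` (m/s; `NA`
#'   for a perfect 3-point fit with zero residual variance it is 0).
#' @export
estimate_bubble_velocity <- function(times, positions) {
  if (length(times) < 3L || length(positions) != length(times)) {
    stop("need at least 3 (time, position) pairs", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing (zero time span not allowed)",
         call. = FALSE)
  }
  fit <- stats::lm(positions ~ times)
  # noiseless tracks (a perfect line) are a supported input
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })$coefficients
  list(velocity = unname(sm["times", "Estimate"]),
       stderr   = unname(sm["times", "Std. Error"]))
}

#' Nominal hydraulic conductivity from a chamber run
#'
#' Applies the Darcy-law expression for the chamber:
#' \deqn{K' = (b/d)^2 \, w \, \frac{dx/dt}{\rho g h}}
#' where the `(b/d)^2` factor converts the bubble velocity in the tracking
#' tube into the filtration velocity through the exposed tissue area.
#'
#' A negative velocity (bubble drifting backwards, i.e. net flow into the
#' feeding side) is physically a leak suspect: the signed result is
#' returned with a warning rather than rejected, since leakage is screened
#' separately on the bench.
#'
#' @param m An [ussing_measurement()].
#' @param velocity Bubble velocity dx/dt in m/s.
#' @return Nominal conductivity K' in m^2/Pa.s.
#' @export
nominal_conductivity <- function(m, velocity) {
  stopifnot(inherits(m, "ussing_measurement"), is.numeric(velocity))
  if (m$h <= 0) stop("zero or negative pressure head 'h'", call. = FALSE)
  if (any(velocity < 0)) {
    warning("negative bubble velocity: leak suspected; returning signed K'",
            call. = FALSE)
  }
  (m$b / m$d)^2 * m$w * velocity / (m$rho * m$g * m$h)
}

# viscosity anchors for PBS ~ water: (degC, Pa.s)
.pbs_anchors <- list(T = c(18, 25), mu = c(1.1e-3, 8.9e-4))

#' PBS buffer viscosity at room temperature
#'
#' PBS viscosity is taken equal to that of water and interpolated linearly
#' between the two tabulated anchors 1.1e-3 Pa.s at 18 degC and 8.9e-4 Pa.s
#' at 25 degC. Outside that range the line is extrapolated with a warning.
#'
#' @param temperature_C Temperature in Celsius.
#' @return Dynamic viscosity in Pa.s (vectorized).
#' @export
pbs_viscosity <- function(temperature_C) {
  if (any(temperature_C < 18 | temperature_C > 25)) {
    warning("temperature outside [18, 25] degC; extrapolating viscosity",
            call. = FALSE)
  }
  a <- .pbs_anchors
  slope <- diff(a$mu) / diff(a$T)
  a$mu[1] + slope * (temperature_C - a$T[1])
}

#' Viscosity correction of nominal conductivity
#'
#' Rescales the nominal conductivity measured with PBS at room temperature
#' to the in-vivo estimate using the interstitial-fluid viscosity at body
#' temperature: \eqn{K = (\mu_{PBS}/\mu_{IF}) K'}.
#'
#' @param K_nominal Nominal conductivity K' in m^2/Pa.s.
#' @param mu_pbs PBS viscosity in Pa.s.
#' @param mu_if Interstitial-fluid viscosity in Pa.s (default 3.5e-3).
#' @return Corrected conductivity K in m^2/Pa.s.
#' @export
viscosity_correct <- function(K_nominal, mu_pbs, mu_if = 3.5e-3) {
  if (any(mu_pbs <= 0) || any(mu_if <= 0)) {
    stop("viscosities must be strictly positive", call. = FALSE)
  }
  (mu_pbs / mu_if) * K_nominal
}

#' Full conductivity estimate for one chamber run
#'
#' Chains velocity estimation, the nominal Darcy conversion and the
#' viscosity correction for a single measurement.
#'
#' @param m An [ussing_measurement()].
#' @param mu_if Interstitial-fluid viscosity in Pa.s.
#' @return An object of class `conductivity_result`: a list with
#'   `sample_id`, `velocity`, `velocity_stderr` (m/s), `mu_pbs`, `mu_if`
#'   (Pa.s), `K_nominal`, `K_corrected` (m^2/Pa.s) and the logical
#'   `leak_suspect` (negative net velocity).
#' @export
measure_conductivity <- function(m, mu_if = 3.5e-3) {
  stopifnot(inherits(m, "ussing_measurement"))
  v <- estimate_bubble_velocity(m$times, m$positions)
  leak <- v$velocity < 0
  Kn <- withCallingHandlers(
    nominal_conductivity(m, v$velocity),
    warning = function(w) if (leak) invokeRestart("muffleWarning")
  )
  if (leak) {
    warning("sample ", m$sample_id,
            ": negative net velocity, leak suspected", call. = FALSE)
  }
  mu_pbs <- pbs_viscosity(m$temperature_C)
  structure(
    list(sample_id = m$sample_id,
         velocity = v$velocity, velocity_stderr = v$stderr,
         mu_pbs = mu_pbs, mu_if = mu_if,
         K_nominal = Kn,
         K_corrected = viscosity_correct(Kn, mu_pbs, mu_if),
         leak_suspect = leak),
    class = "conductivity_result"
  )
}

#' @export
print.conductivity_result <- function(x, ...) {
  cat("<conductivity_result>", x$sample_id, "\n")
  cat(sprintf("  velocity    %.4g +/- %.2g m/s\n", x$velocity,
              x$velocity_stderr))
  cat(sprintf("  K_nominal   %.4g m^2/Pa.s\n", x$K_nominal))
  cat(sprintf("  K_corrected %.4g m^2/Pa.s  (mu_PBS %.3g / mu_IF %.3g)\n",
              x$K_corrected, x$mu_pbs, x$mu_if))
  if (isTRUE(x$leak_suspect)) cat("  ** leak suspect: negative velocity\n")
  invisible(x)
}

#' Read bubble tracks from CSV
#'
#' Expects one row per frame with columns `sample_id`, `time_s`,
#' `position_m` and optionally `temperature_C` (constant within a sample).
#' Chamber geometry is supplied through `chamber` (a named list overriding
#' the [ussing_measurement()] defaults), typically from the `chamber`
#' section of a run config.
#'
#' @param path CSV file path. Lines starting with `#` are ignored.
#' @param chamber Named list of geometry/fluid overrides
#'   (`w`, `d`, `b`, `rho`, `h`, `g`, `temperature_C`).
#' @return A list of `ussing_measurement` objects, one per `sample_id`.
#' @export
read_bubble_tracks <- function(path, chamber = list()) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "time_s", "position_m")
  if (!all(need %in% names(df))) {
    stop("bubble-track CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$sample_id), function(g) {
    g <- g[order(g$time_s), ]
    args <- c(list(sample_id = as.character(g$sample_id[1]),
                   times = g$time_s, positions = g$position_m),
              chamber)
    if ("temperature_C" %in% names(g) && is.null(chamber$temperature_C)) {
      args$temperature_C <- g$temperature_C[1]
    }
    do.call(ussing_measurement, args)
  })
}

#' Tabulate conductivity results for a set of measurements
#'
#' @param measurements List of [ussing_measurement()] objects.
#' @param mu_if Interstitial-fluid viscosity in Pa.s.
#' @return A data.frame with one row per sample: `sample_id`, `velocity`,
#'   `velocity_stderr`, `K_nominal`, `K_corrected`, `mu_pbs`, `mu_if`,
#'   `leak_suspect`.
#' @export
conductivity_table <- function(measurements, mu_if = 3.5e-3) {
  rows <- lapply(measurements, function(m) {
    r <- measure_conductivity(m, mu_if = mu_if)
    data.frame(sample_id = r$sample_id,
               velocity = r$velocity, velocity_stderr = r$velocity_stderr,
               K_nominal = r$K_nominal, K_corrected = r$K_corrected,
               mu_pbs = r$mu_pbs, mu_if = r$mu_if,
               leak_suspect = r$leak_suspect)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
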