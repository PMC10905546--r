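#' Validate a tissue-sample cohort table
#'
#' A cohort is a plain data.frame with one row per measured slice and
#' columns `sample_id`, `tumor_type`, `K` (m^2/Pa.s), `collagen_pct`,
#' `cell_pct`, `fibroblast_pct` (area percentages in \[0, 100\]).
#' Recognized tumor-type labels are `PC`, `PM-CRC`, `PM-CRC-AW`, `PM-SB`,
#' `PM-OC`, `OM-SB`, `NP`, but arbitrary labels are accepted.
#'
#' @param samples A data.frame of tissue samples.
#' @return The validated data.frame, invisibly coerced types.
#' @export
validate_cohort <- function(samples) {
  need <- c("sample_id", "tumor_type", "K",
            "collagen_pct", "cell_pct", "fibroblast_pct")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    stop("cohort needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) == 0) stop("empty cohort", call. = FALSE)
  dens <- as.matrix(samples[, c("collagen_pct", "cell_pct",
                                "fibroblast_pct")])
  if (any(dens < 0 | dens > 100)) {
    stop("area densities must lie in [0, 100] %", call. = FALSE)
  }
  if (any(samples$K <= 0)) stop("K values must be > 0", call. = FALSE)
  samples
}

#' Simple linear regression with correlation summaries
#'
#' Fits `y ~ x` by ordinary least squares and reports the quantities used
#' throughout the correlation analysis: signed Pearson r, R^2, the
#' two-sided p-value of the slope t-test (n - 2 df), slope, intercept and
#' a standard error.
#'
#' @param x Predictor values.
#' @param y Response values, same length.
#' @param se_type Which quantity to report as `SE`: `"slope"` (standard
#'   error of the slope estimate, the default) or `"estimate"` (residual
#'   standard error of the fit).
#' @return An object of class `simple_regression`: a list with `slope`,
#'   `intercept`, `r`, `abs_r`, `R2`, `p`, `SE`, `se_slope`,
#'   `se_estimate`, `n`.
#' @export
#' @examples
#' fit_simple_regression(c(0, 1, 2), c(0, 2, 4))   # exact line, R2 = 1
fit_simple_regression <- function(x, y, se_type = c("slope", "estimate")) {
  se_type <- match.arg(se_type)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) {
    stop("need at least 3 complete (x, y) pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate input: 'x' is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # exact linear inputs (R2 = 1) are legitimate here; drop summary.lm's
  # "essentially perfect fit" warning for that case
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  slope <- unname(stats::coef(fit)[2])
  r <- if (stats::sd(y) == 0) 0 else unname(stats::cor(x, y))
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r = r, abs_r = abs(r),
         R2 = unname(sm$r.squared),
         p = unname(sm$coefficients[2, 4]),
         SE = if (se_type == "slope") unname(sm$coefficients[2, 2])
              else sm$sigma,
         se_slope = unname(sm$coefficients[2, 2]),
         se_estimate = sm$sigma,
         n = n),
    class = "simple_regression"
  )
}

#' @export
print.simple_regression <- function(x, ...) {
  cat(sprintf(
    "<simple_regression> n=%d  slope=%.4g  int=%.4g  r=%.3f  R2=%.3f  p=%.3g\n",
    x$n, x$slope, x$intercept, x$r, x$R2, x$p))
  invisible(x)
}

.tme_pairs <- list(
  fiber_vs_cell       = c(y = "collagen_pct",   x = "cell_pct"),
  fiber_vs_fibroblast = c(y = "collagen_pct",   x = "fibroblast_pct"),
  cell_vs_fibroblast  = c(y = "cell_pct",       x = "fibroblast_pct"),
  K_vs_fiber          = c(y = "K",              x = "collagen_pct"),
  K_vs_cell           = c(y = "K",              x = "cell_pct"),
  K_vs_fibroblast     = c(y = "K",              x = "fibroblast_pct")
)

#' Correlation table across TME elements and conductivity
#'
#' Fits every pairwise simple regression among the three
#' tumor-microenvironment densities (collagen fiber, cell, fibroblast) and
#' between hydraulic conductivity K and each density, for the pooled
#' cohort and for each tumor-type subset with at least 3 samples. Groups
#' with fewer samples are emitted as rows with `status = "too_few"` and
#' `NA` statistics rather than dropped.
#'
#' Because measured K spans more than a decade, the K regressions are
#' fitted on `log10(K)` by default (`log10_K = FALSE` fits linear K).
#' Both signed r and |r| are reported: published tables often tabulate
#' |r| next to a signed parameter estimate.
#'
#' @param samples Cohort data.frame (see [validate_cohort()]).
#' @param groupings Character vector of tumor types to analyse as
#'   subsets, or `NULL` for all types present in the data. The pooled
#'   grouping `"all"` is always included.
#' @param log10_K Fit K pairs on the log10 scale (default `TRUE`).
#' @param se_type Passed to [fit_simple_regression()].
#' @return A data.frame with one row per pair x grouping: `grouping`,
#'   `pair`, `n`, `r`, `abs_r`, `R2`, `p`, `SE`, `intercept`, `slope`,
#'   `status`.
#' @export
correlation_table <- function(samples, groupings = NULL, log10_K = TRUE,
                              se_type = c("slope", "estimate")) {
  se_type <- match.arg(se_type)
  samples <- validate_cohort(samples)
  if (is.null(groupings)) groupings <- unique(as.character(samples$tumor_type))
  groups <- c(list(all = samples),
              stats::setNames(
                lapply(groupings,
                       function(g) samples[samples$tumor_type == g, ]),
                groupings))
  rows <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    for (pname in names(.tme_pairs)) {
      pair <- .tme_pairs[[pname]]
      y <- g[[pair[["y"]]]]
      x <- g[[pair[["x"]]]]
      if (pair[["y"]] == "K" && log10_K) y <- log10(y)
      if (nrow(g) < 3 || stats::sd(x) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          grouping = gname, pair = pname, n = nrow(g),
          r = NA_real_, abs_r = NA_real_, R2 = NA_real_, p = NA_real_,
          SE = NA_real_, intercept = NA_real_, slope = NA_real_,
          status = if (nrow(g) < 3) "too_few" else "constant_predictor")
      } else {
        f <- fit_simple_regression(x, y, se_type = se_type)
        rows[[length(rows) + 1L]] <- data.frame(
          grouping = gname, pair = pname, n = f$n,
          r = f$r, abs_r = f$abs_r, R2 = f$R2, p = f$p,
          SE = f$SE, intercept = f$intercept, slope = f$slope,
          status = "ok")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
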