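# Independent oracles used to cross-check the implementation. These are
# written from closed forms, not from the package's code paths.

# complementary error function (not in base R)
erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

# hand-written least squares: slope, intercept, slope SE, r, R2, p
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  tstat <- slope / se_slope
  list(slope = slope, intercept = intercept, se_slope = se_slope,
       se_estimate = sqrt(s2), r = r, R2 = r^2,
       p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# analytic steady IFP in a uniform sphere of radius R with Starling
# source everywhere, no lymphatics, p = 0 at r = R:
#   p(r) = p_e [1 - (R/r) sinh(a r/R)/sinh(a)],  a = R sqrt(LpSV/K)
# evaluated in overflow-safe form.
ifp_analytic <- function(r, R, K, LpSV, p_e) {
  a <- R * sqrt(LpSV / K)
  x <- r / R
  s <- ifelse(x < 1e-12, a / sinh(a),
              (1 / x) * exp(a * (x - 1)) * (1 - exp(-2 * a * x)) /
                (1 - exp(-2 * a)))
  p_e * (1 - s)
}

# transport parameters describing one uniform vascularized medium
# (tumor constants apply in every region, no lymphatics anywhere)
uniform_params <- function() {
  transport_params(
    Lp_normal = 2.1e-11, SV_normal = 2e4,
    sigma_normal = 0.82, pi_i_normal = 2000,
    vascular_on = c(necrotic = TRUE, hypoxic = TRUE, viable = TRUE,
                    normal = TRUE),
    lymphatic_on = c(necrotic = FALSE, hypoxic = FALSE, viable = FALSE,
                     normal = FALSE))
}
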