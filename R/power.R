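# Analytic power approximation for two-sample MR, following the
# non-centrality-parameter approach of the mRnd-style calculators
# (Brion et al., Int J Epidemiol 2013).

# Two-sided power of a z-test at non-centrality ncp = lambda (so the test
# statistic is N(sqrt(lambda), 1)); identical to the 1-df chi-square form
# 1 - pchisq(qchisq(1 - alpha, 1), 1, ncp = lambda).
ncp_power <- function(ncp, alpha) {
  zcrit <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-zcrit + sqrt(ncp)) + stats::pnorm(-zcrit - sqrt(ncp))
}

check_power_args <- function(n, r2_gx, alpha) {
  if (n <= 0) stop("power: n must be positive")
  if (r2_gx <= 0 || r2_gx >= 1) stop("power: r2_gx must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("power: alpha must be in (0, 1)")
}

#' MR power for a continuous outcome
#'
#' Non-centrality approximation: with both traits standardized, the IVW
#' estimator's squared signal-to-noise is `NCP = n * r2_gx * beta^2`, and
#' power is the two-sided normal tail mass
#' `pnorm(-z + sqrt(NCP)) + pnorm(-z - sqrt(NCP))` at `z = qnorm(1 -
#' alpha/2)`. At `beta = 0` this returns exactly `alpha`.
#'
#' @param n Outcome-study sample size.
#' @param r2_gx Fraction of exposure variance explained by the instruments,
#'   in (0, 1).
#' @param beta Hypothesized causal effect, SD outcome per SD exposure.
#' @param alpha Test size (default 0.05).
#' @return Power, in (0, 1).
#' @export
mr_power_continuous <- function(n, r2_gx, beta, alpha = 0.05) {
  check_power_args(n, r2_gx, alpha)
  ncp_power(n * r2_gx * beta^2, alpha)
}

#' MR power for a binary outcome
#'
#' The binary-outcome variant of the same calculator. The odds ratio is
#' first attenuated to an approximate risk-difference effect per SD of
#' exposure,
#' `b = K * (OR / (1 + K * (OR - 1)) - 1)` with case fraction `K`, whose
#' sampling variance under the instrumented design is
#' `v = (K * (1 - K) - b^2) / (n * r2_gx)`; power then follows from
#' `NCP = b^2 / v` exactly as in the continuous case. For small effects
#' `b ~ K * (1 - K) * log(OR)`. At `OR = 1` this returns exactly `alpha`.
#'
#' @param n Outcome-study sample size (cases + controls).
#' @param r2_gx Fraction of exposure variance explained by the instruments.
#' @param or Hypothesized causal odds ratio per SD of exposure; must be
#'   positive.
#' @param case_fraction Proportion of cases in the outcome study, in
#'   (0, 1).
#' @param alpha Test size (default 0.05).
#' @return Power, in (0, 1).
#' @export
mr_power_binary <- function(n, r2_gx, or, case_fraction, alpha = 0.05) {
  check_power_args(n, r2_gx, alpha)
  if (or <= 0) stop("power: odds ratio must be positive")
  if (case_fraction <= 0 || case_fraction >= 1) {
    stop("power: case_fraction must be in (0, 1)")
  }
  K <- case_fraction
  b <- K * (or / (1 + K * (or - 1)) - 1)
  v <- (K * (1 - K) - b^2) / (n * r2_gx)
  ncp_power(b^2 / v, alpha)
}
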