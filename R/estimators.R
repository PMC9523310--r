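# Causal-effect estimators for two-sample MR: per-SNP Wald ratios,
# fixed-effect IVW pooling, MR-Egger regression, the bootstrap weighted
# median, and the supporting scale/significance helpers.

# 97.5% normal quantile used for every confidence interval in the package.
# Fixed to 6 decimals (rather than calling qnorm each time) so that CI
# bounds are bit-reproducible across platforms and stated in the docs.
CI_Z <- 1.959964

#' Construct an MR estimate record
#'
#' One-row data frame holding a causal-effect estimate and its uncertainty.
#' `z`, `pvalue` and the 95% confidence bounds are derived from `theta` and
#' `se` under a normal approximation; the CI multiplier is fixed at
#' 1.959964.
#'
#' @param method Label: one of `"wald_ratio"`, `"ivw_fixed"`,
#'   `"mr_egger_slope"`, `"mr_egger_intercept"`, `"weighted_median"`.
#' @param theta Point estimate. SD outcome per SD exposure for continuous
#'   outcomes; log odds per SD exposure for binary outcomes.
#' @param se Standard error of `theta`; must be positive (or `NA` when an
#'   estimator is run in point-estimate-only mode).
#' @param n_snps Number of instruments behind the estimate.
#' @return A one-row `data.frame` with columns `method`, `n_snps`, `theta`,
#'   `se`, `z`, `pvalue`, `ci_low`, `ci_high`.
#' @export
mr_estimate <- function(method, theta, se, n_snps) {
  stopifnot(length(theta) == 1L, length(se) == 1L)
  if (!is.na(se) && se <= 0) {
    stop("mr_estimate: se must be > 0, got ", se)
  }
  z <- theta / se
  data.frame(
    method = method,
    n_snps = as.integer(n_snps),
    theta = theta,
    se = se,
    z = z,
    pvalue = pvalue_two_sided(z),
    ci_low = theta - CI_Z * se,
    ci_high = theta + CI_Z * se,
    stringsAsFactors = FALSE
  )
}

#' Two-sided normal p-value
#'
#' @param z Standardized statistic (finite, or `NA`).
#' @return `2 * pnorm(-|z|)`, in (0, 1].
#' @export
pvalue_two_sided <- function(z) {
  2 * stats::pnorm(-abs(z))
}

#' Per-SNP Wald ratio estimates
#'
#' The ratio of the SNP-outcome association to the SNP-exposure association,
#' computed for every row of a harmonized instrument table. The standard
#' error uses the delta method: first order `se_outcome / |beta_exposure|`,
#' or second order
#' `sqrt(se_outcome^2/beta_exposure^2 +
#'        beta_outcome^2 * se_exposure^2 / beta_exposure^4)`.
#'
#' First order is the default, matching common two-sample practice where
#' instruments are strong and the exposure-side sampling error is a
#' second-order contribution.
#'
#' @param h Harmonized instrument table (see [harmonize()]): columns
#'   `rsid`, `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param se_order `"first"` or `"second"` delta-method expansion.
#' @return A data frame with one [mr_estimate()] row per instrument plus a
#'   leading `rsid` column.
#' @export
wald_ratio <- function(h, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  if (any(h$beta_exposure == 0)) {
    stop("wald_ratio: beta_exposure is zero for ",
         paste(h$rsid[h$beta_exposure == 0], collapse = ", "),
         "; the ratio is undefined")
  }
  theta <- h$beta_outcome / h$beta_exposure
  se <- if (se_order == "first") {
    h$se_outcome / abs(h$beta_exposure)
  } else {
    sqrt(h$se_outcome^2 / h$beta_exposure^2 +
           h$beta_outcome^2 * h$se_exposure^2 / h$beta_exposure^4)
  }
  out <- do.call(rbind, lapply(seq_along(theta), function(j) {
    mr_estimate("wald_ratio", theta[j], se[j], 1L)
  }))
  cbind(data.frame(rsid = h$rsid, stringsAsFactors = FALSE), out)
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Pools per-SNP Wald ratios with weights `1/se^2`:
#' `theta = sum(w * theta_j) / sum(w)`, `se = sum(w)^(-1/2)`. With a single
#' instrument this reproduces that instrument's Wald ratio exactly.
#'
#' @param per_snp Data frame of per-SNP estimates from [wald_ratio()]
#'   (columns `theta`, `se`).
#' @return A one-row [mr_estimate()] with method `"ivw_fixed"`.
#' @export
ivw_fixed <- function(per_snp) {
  if (nrow(per_snp) < 1L) stop("ivw_fixed: no per-SNP estimates supplied")
  if (any(per_snp$se <= 0)) stop("ivw_fixed: all SEs must be > 0")
  w <- per_snp$se^-2
  theta <- sum(w * per_snp$theta) / sum(w)
  mr_estimate("ivw_fixed", theta, sum(w)^-0.5, nrow(per_snp))
}

#' Cochran's Q heterogeneity statistic for a fixed-effect pool
#'
#' @param per_snp Per-SNP estimates (from [wald_ratio()]).
#' @param pooled The pooled estimate (from [ivw_fixed()]).
#' @return List with `Q`, `df = n - 1`, and the chi-square upper-tail
#'   `pvalue`.
#' @export
heterogeneity_q <- function(per_snp, pooled) {
  n <- nrow(per_snp)
  if (n < 2L) stop("heterogeneity_q: need at least 2 per-SNP estimates")
  w <- per_snp$se^-2
  Q <- sum(w * (per_snp$theta - pooled$theta)^2)
  df <- n - 1L
  list(Q = Q, df = df, pvalue = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with an unconstrained intercept, weights `1/se_outcome^2`. Instruments
#' are first oriented so every exposure effect is positive (both betas
#' negated where needed), which the intercept interpretation requires. A
#' non-null intercept indicates directional horizontal pleiotropy and that
#' the IVW estimate may be invalid; the slope remains a consistent causal
#' estimate when instrument strength is independent of the direct effects
#' (InSIDE).
#'
#' Standard errors use multiplicative residual inflation with the residual
#' scale floored at 1, the usual Egger convention: under-dispersion never
#' shrinks the SEs below the fixed-effect ones.
#'
#' @param instruments Harmonized instrument table with at least 3 rows.
#' @return List with elements `slope` and `intercept`, each an
#'   [mr_estimate()] row (`mr_egger_slope`, `mr_egger_intercept`).
#' @export
mr_egger <- function(instruments) {
  n <- nrow(instruments)
  if (n < 3L) stop("mr_egger: at least 3 instruments required, got ", n)
  sgn <- sign(instruments$beta_exposure)
  bx <- instruments$beta_exposure * sgn
  by <- instruments$beta_outcome * sgn
  if (length(unique(bx)) == 1L) {
    stop("mr_egger: all exposure effects identical after orientation; ",
         "the regression design is degenerate")
  }
  w <- instruments$se_outcome^-2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # summary() SEs already carry the residual scale multiplicatively;
  # dividing by min(sigma, 1) floors that scale at 1.
  infl <- min(sm$sigma, 1)
  co <- sm$coefficients
  list(
    intercept = mr_estimate("mr_egger_intercept",
                            co[1, 1], co[1, 2] / infl, n),
    slope = mr_estimate("mr_egger_slope",
                        co[2, 1], co[2, 2] / infl, n)
  )
}

# Weighted median of values x with weights w (summing to 1): interpolate x
# against the centred cumulative weights s_j = cumsum(w) - w/2 at 0.5.
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(s)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimator
#'
#' The 50% weighted quantile of the per-SNP Wald ratios, with first-order
#' inverse-variance weights `(se_outcome/|beta_exposure|)^-2` normalized to
#' sum to one. Consistent even when up to 50% of the weight comes from
#' invalid (pleiotropic) instruments. The standard error is the standard
#' deviation of the estimate over `n_boot` parametric-bootstrap draws that
#' resample both exposure and outcome effects from their sampling
#' distributions.
#'
#' @param instruments Harmonized instrument table with at least 3 rows.
#' @param n_boot Bootstrap replicates for the SE (default 10000). `n_boot =
#'   0` skips the bootstrap and returns the point estimate with `NA` se and
#'   p-value — useful inside simulation studies that only need the point
#'   estimate.
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @return A one-row [mr_estimate()] with method `"weighted_median"`.
#' @export
weighted_median <- function(instruments, n_boot = 10000L, seed = NULL) {
  n <- nrow(instruments)
  if (n < 3L) stop("weighted_median: at least 3 instruments required, got ", n)
  ratio <- instruments$beta_outcome / instruments$beta_exposure
  w <- (instruments$se_outcome / abs(instruments$beta_exposure))^-2
  theta <- weighted_median_point(ratio, w)
  if (n_boot == 0L) {
    out <- mr_estimate("weighted_median", theta, 1, n)
    out$se <- NA_real_
    out$z <- NA_real_
    out$pvalue <- NA_real_
    out$ci_low <- NA_real_
    out$ci_high <- NA_real_
    return(out)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  boot <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(n, instruments$beta_exposure, instruments$se_exposure)
    by <- stats::rnorm(n, instruments$beta_outcome, instruments$se_outcome)
    wb <- (instruments$se_outcome / abs(bx))^-2
    weighted_median_point(by / bx, wb)
  }, numeric(1))
  mr_estimate("weighted_median", theta, stats::sd(boot), n)
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' Exponentiates the point estimate and both confidence bounds of an
#' estimate expressed as log odds per SD of exposure.
#'
#' @param est An [mr_estimate()] row on the log-odds scale.
#' @return List with `or`, `or_ci_low`, `or_ci_high`.
#' @export
to_odds_ratio <- function(est) {
  list(or = exp(est$theta),
       or_ci_low = exp(est$ci_low),
       or_ci_high = exp(est$ci_high))
}
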