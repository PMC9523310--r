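# Shared fixtures and independent oracles.
#
# The oracles recompute the estimators from their defining formulas with
# explicit sums / normal equations, sharing no code with the package
# implementations they check.

# random harmonized instrument table
random_harmonized <- function(n, seed) {
  set.seed(seed)
  data.frame(
    rsid = sprintf("rs%03d", seq_len(n)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = stats::runif(n, -0.4, 0.4),
    se_exposure = stats::runif(n, 0.005, 0.03),
    beta_outcome = stats::rnorm(n, 0, 0.2),
    se_outcome = stats::runif(n, 0.01, 0.08),
    eaf_exposure = stats::runif(n, 0.1, 0.9),
    eaf_outcome = stats::runif(n, 0.1, 0.9),
    flipped = FALSE, palindromic = FALSE,
    stringsAsFactors = FALSE
  )
}

# inverse-variance weighted mean by explicit summation
ivw_oracle <- function(theta, se) {
  w <- 1 / se^2
  list(theta = sum(w * theta) / sum(w), se = 1 / sqrt(sum(w)))
}

# weighted least squares of by on bx (intercept included) via the normal
# equations, with the Egger SE convention: residual scale floored at 1
egger_oracle <- function(bx, by, se_outcome) {
  s <- sign(bx)
  bx <- bx * s
  by <- by * s
  w <- 1 / se_outcome^2
  X <- cbind(1, bx)
  XtWX <- t(X) %*% (w * X)
  coefs <- solve(XtWX, t(X) %*% (w * by))
  res <- by - X %*% coefs
  sigma2 <- sum(w * res^2) / (length(bx) - 2)
  ses <- unname(sqrt(diag(solve(XtWX)))) * max(sqrt(sigma2), 1)
  list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
       se_intercept = ses[1], se_slope = ses[2])
}

# associations table built directly in code
make_assocs <- function(rsid, a1, a2, beta, se,
                        pvalue = pvalue_two_sided(beta / se),
                        eaf = NA_real_, n = NA_integer_,
                        trait = "trait", trait_type = "continuous") {
  data.frame(rsid = rsid, effect_allele = a1, other_allele = a2,
             beta = beta, se = se, pvalue = pvalue, eaf = eaf, n = n,
             trait = trait, trait_type = trait_type,
             stringsAsFactors = FALSE)
}

# view a harmonized table's outcome side as an associations table, so the
# output of harmonize() can be fed back into harmonize()
outcome_view <- function(h) {
  make_assocs(h$rsid, h$effect_allele, h$other_allele, h$beta_outcome,
              h$se_outcome, eaf = h$eaf_outcome)
}

exposure_view <- function(h) {
  make_assocs(h$rsid, h$effect_allele, h$other_allele, h$beta_exposure,
              h$se_exposure, eaf = h$eaf_exposure)
}
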