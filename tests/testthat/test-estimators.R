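h_one <- function(bx, sx, by, sy, rsid = "rs1") {
  data.frame(rsid = rsid, effect_allele = "A", other_allele = "G",
             beta_exposure = bx, se_exposure = sx, beta_outcome = by,
             se_outcome = sy, eaf_exposure = 0.3, eaf_outcome = 0.3,
             flipped = FALSE, palindromic = FALSE, stringsAsFactors = FALSE)
}

test_that("wald_ratio matches the ratio and both delta-method orders", {
  h <- h_one(0.5, 0.05, 0.4, 0.1)
  first <- wald_ratio(h)
  expect_equal(first$theta, 0.8)
  expect_equal(first$se, 0.1 / 0.5)
  second <- wald_ratio(h, se_order = "second")
  expect_equal(second$theta, 0.8)
  expect_equal(second$se, sqrt(0.04 + 0.0064), tolerance = 1e-12)
  expect_equal(round(second$se, 5), 0.21541)
  expect_error(wald_ratio(h_one(0, 0.05, 0.4, 0.1)), "rs1")
})

test_that("IVW pools by inverse variance and reduces to the Wald ratio for one SNP", {
  per <- rbind(mr_estimate("wald_ratio", 1, 1, 1L),
               mr_estimate("wald_ratio", 3, 1, 1L))
  est <- ivw_fixed(per)
  expect_equal(est$theta, 2)
  expect_equal(est$se, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(est$n_snps, 2L)

  h <- h_one(0.5, 0.05, 0.4, 0.1)
  single <- wald_ratio(h)
  pooled <- ivw_fixed(single)
  expect_equal(pooled$theta, single$theta)
  expect_equal(pooled$se, single$se)

  const <- rbind(mr_estimate("wald_ratio", 2, 0.5, 1L),
                 mr_estimate("wald_ratio", 2, 0.1, 1L),
                 mr_estimate("wald_ratio", 2, 2, 1L))
  expect_equal(ivw_fixed(const)$theta, 2)
  expect_error(ivw_fixed(const[0, ]), "no per-SNP")
})

test_that("IVW matches the explicit-sum oracle on random inputs", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(2:20, 1)
    theta <- rnorm(n)
    se <- runif(n, 0.05, 2)
    per <- do.call(rbind, lapply(seq_len(n), function(j) {
      mr_estimate("wald_ratio", theta[j], se[j], 1L)
    }))
    est <- ivw_fixed(per)
    oracle <- ivw_oracle(theta, se)
    expect_equal(est$theta, oracle$theta, tolerance = 1e-12)
    expect_equal(est$se, oracle$se, tolerance = 1e-12)
  }
})

test_that("MR-Egger recovers exact affine structure", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h0 <- h_one(bx, 0.01, 0.5 * bx, c(0.02, 0.05, 0.03, 0.04),
              rsid = sprintf("rs%d", 1:4))
  # summary.lm warns about the (intentionally) perfect fit
  eg <- suppressWarnings(mr_egger(h0))
  expect_equal(eg$slope$theta, 0.5, tolerance = 1e-12)
  expect_equal(eg$intercept$theta, 0, tolerance = 1e-12)

  h1 <- h_one(bx[1:3], 0.01, 0.1 + 0.5 * bx[1:3], c(0.02, 0.05, 0.03),
              rsid = sprintf("rs%d", 1:3))
  eg <- suppressWarnings(mr_egger(h1))
  expect_equal(eg$slope$theta, 0.5, tolerance = 1e-12)
  expect_equal(eg$intercept$theta, 0.1, tolerance = 1e-12)
})

test_that("MR-Egger matches the weighted normal-equations oracle", {
  for (s in 1:25) {
    h <- random_harmonized(sample(3:15, 1), seed = 100 + s)
    eg <- mr_egger(h)
    oracle <- egger_oracle(h$beta_exposure, h$beta_outcome, h$se_outcome)
    expect_equal(eg$slope$theta, oracle$slope, tolerance = 1e-10)
    expect_equal(eg$intercept$theta, oracle$intercept, tolerance = 1e-10)
    expect_equal(eg$slope$se, oracle$se_slope, tolerance = 1e-10)
    expect_equal(eg$intercept$se, oracle$se_intercept, tolerance = 1e-10)
  }
})

test_that("MR-Egger rejects degenerate designs", {
  expect_error(mr_egger(h_one(0.2, 0.01, 0.1, 0.02)), "3 instruments")
  same <- h_one(c(0.2, 0.2, -0.2), 0.01, c(0.1, 0.12, -0.09), 0.02,
                rsid = sprintf("rs%d", 1:3))
  expect_error(mr_egger(same), "degenerate")
})

test_that("weighted median interpolates the weighted quantile at 0.5", {
  # equal weights: the simple median
  h <- h_one(c(1, 1, 1), 0.01, c(1, 2, 9), 1, rsid = sprintf("rs%d", 1:3))
  expect_equal(weighted_median(h, n_boot = 0)$theta, 2)
  # hand-computed interpolation: ratios {1, 2}, weights {0.25, 0.75}
  # s = {0.125, 0.625}; at 0.5: 1 + (0.5 - 0.125) / 0.5 = 1.75
  expect_equal(ironmr:::weighted_median_point(c(1, 2), c(0.25, 0.75)), 1.75)
  # near-total weight on one ratio pulls the quantile toward it:
  # s = {0.49, 0.99}, so theta = 1 + (0.5 - 0.49) / 0.5 * 4 = 1.08
  expect_equal(ironmr:::weighted_median_point(c(1, 5), c(0.98, 0.02)), 1.08)
  # a degenerate full weight returns that ratio exactly
  expect_equal(ironmr:::weighted_median_point(c(1, 5), c(1, 0)), 1)
  expect_error(weighted_median(h[1:2, ]), "3 instruments")
})

test_that("weighted median equals the simple median under equal weights", {
  for (s in 1:10) {
    set.seed(300 + s)
    n <- sample(c(5, 9, 15), 1)  # odd, so the simple median is unique
    ratios <- rnorm(n)
    h <- h_one(rep(1, n), 0.01, ratios, 1, rsid = sprintf("rs%d", 1:n))
    expect_equal(weighted_median(h, n_boot = 0)$theta, median(ratios))
  }
})

test_that("weighted-median bootstrap SE is seed-reproducible and positive", {
  h <- random_harmonized(8, seed = 77)
  a <- weighted_median(h, n_boot = 500, seed = 42)
  b <- weighted_median(h, n_boot = 500, seed = 42)
  expect_equal(a$se, b$se)
  expect_gt(a$se, 0)
  c <- weighted_median(h, n_boot = 500, seed = 43)
  expect_false(isTRUE(all.equal(a$se, c$se)))
})

test_that("odds-ratio conversion exponentiates estimate and CI", {
  est <- mr_estimate("ivw_fixed", 0, 0.1, 3L)
  expect_equal(to_odds_ratio(est)$or, 1)
  est2 <- mr_estimate("ivw_fixed", log(2), log(2) / 1.959964, 3L)
  or2 <- to_odds_ratio(est2)
  expect_equal(or2$or, 2)
  expect_equal(or2$or_ci_low, 1, tolerance = 1e-12)
  expect_equal(or2$or_ci_high, 4, tolerance = 1e-12)
  expect_equal(round(exp(0.63658), 2), 1.89)
})

test_that("two-sided p-values follow the normal tail", {
  expect_equal(pvalue_two_sided(0), 1)
  expect_equal(pvalue_two_sided(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(pvalue_two_sided(6.6), 2 * pnorm(-6.6))
  expect_equal(pvalue_two_sided(6.6), 4.1e-11, tolerance = 0.01)
})

test_that("heterogeneity Q sums weighted squared deviations", {
  per <- rbind(mr_estimate("wald_ratio", 1, 1, 1L),
               mr_estimate("wald_ratio", 3, 1, 1L))
  q <- heterogeneity_q(per, ivw_fixed(per))
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1)
  expect_equal(q$pvalue, pchisq(2, 1, lower.tail = FALSE))

  same <- rbind(mr_estimate("wald_ratio", 2, 0.5, 1L),
                mr_estimate("wald_ratio", 2, 1, 1L))
  q0 <- heterogeneity_q(same, ivw_fixed(same))
  expect_equal(q0$Q, 0)
  expect_equal(q0$pvalue, 1)
  expect_error(heterogeneity_q(per[1, ], ivw_fixed(per)), "at least 2")
})

test_that("every estimator is sign-equivariant in the outcome and SEs are unchanged", {
  h <- random_harmonized(9, seed = 55)
  neg <- h
  neg$beta_outcome <- -h$beta_outcome
  for (f in list(function(x) ivw_fixed(wald_ratio(x)),
                 function(x) mr_egger(x)$slope,
                 function(x) weighted_median(x, n_boot = 0))) {
    a <- f(h)
    b <- f(neg)
    expect_equal(b$theta, -a$theta, tolerance = 1e-12)
    if (!is.na(a$se)) expect_equal(b$se, a$se, tolerance = 1e-12)
  }
})

test_that("rescaling the exposure divides every estimate by the scale factor", {
  h <- random_harmonized(7, seed = 56)
  for (c_scale in c(0.5, 3)) {
    hs <- h
    hs$beta_exposure <- c_scale * h$beta_exposure
    hs$se_exposure <- c_scale * h$se_exposure
    expect_equal(ivw_fixed(wald_ratio(hs))$theta,
                 ivw_fixed(wald_ratio(h))$theta / c_scale,
                 tolerance = 1e-12)
    expect_equal(mr_egger(hs)$slope$theta, mr_egger(h)$slope$theta / c_scale,
                 tolerance = 1e-12)
    expect_equal(weighted_median(hs, n_boot = 0)$theta,
                 weighted_median(h, n_boot = 0)$theta / c_scale,
                 tolerance = 1e-12)
  }
})

test_that("CI bounds use the fixed 1.959964 multiplier", {
  est <- mr_estimate("ivw_fixed", 0.3, 0.1, 3L)
  expect_equal(est$ci_low, 0.3 - 1.959964 * 0.1)
  expect_equal(est$ci_high, 0.3 + 1.959964 * 0.1)
  expect_error(mr_estimate("ivw_fixed", 0.3, -0.1, 3L), "se must be")
})
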