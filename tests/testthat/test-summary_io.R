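test_that("reading a valid table preserves rows, order and normalizes alleles", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp\tea\toa\tb\tstderr\tp",
               "rs1\ta\tg\t0.30\t0.01\t1e-10",
               "rs2\tC\tt\t-0.12\t0.02\t2e-9",
               "rs3\tG\ta\t0.05\t0.015\t0.5"), path)
  got <- read_summary_stats(path, column_map = c(
    rsid = "snp", effect_allele = "ea", other_allele = "oa",
    beta = "b", se = "stderr", pvalue = "p"))
  expect_equal(got$rsid, c("rs1", "rs2", "rs3"))
  expect_equal(got$effect_allele, c("A", "C", "G"))
  expect_equal(got$other_allele, c("G", "T", "A"))
  expect_equal(got$beta, c(0.30, -0.12, 0.05))
})

test_that("delimiter auto-detection handles comma and whitespace files", {
  for (sep in c(",", " ")) {
    path <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(paste("rsid", "effect_allele", "other_allele", "beta",
                       "se", sep = sep),
                 paste("rs1", "A", "G", "0.3", "0.01", sep = sep)), path)
    got <- read_summary_stats(path)
    expect_equal(got$beta, 0.3)
  }
})

test_that("invalid rows are fatal in strict mode, dropped otherwise", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\teffect_allele\tother_allele\tbeta\tse",
               "rs1\tA\tG\t0.3\t0.01",
               "rsBad\tA\tG\t0.3\t0"), path)
  expect_error(read_summary_stats(path), "rsBad")
  expect_warning(got <- read_summary_stats(path, strict = FALSE), "rsBad")
  expect_equal(got$rsid, "rs1")
})

test_that("a missing mapped column is a configuration error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\teffect_allele\tother_allele\tbeta\tse",
               "rs1\tA\tG\t0.3\t0.01"), path)
  expect_error(read_summary_stats(path, column_map = c(beta = "BETA")),
               "BETA")
})

test_that("write + read round-trips all fields", {
  assocs <- make_assocs(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                        beta = c(0.31, -0.118), se = c(0.0123, 0.0456),
                        eaf = c(0.07, 0.66), n = c(48972L, 361194L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(assocs, path)
  got <- read_summary_stats(path)
  expect_equal(got, assocs)
})

test_that("harmonize aligns matched, swapped and strand-flipped alleles", {
  ex <- make_assocs("rs1", "A", "G", 0.3, 0.01, eaf = 0.2)
  # matched alleles: copied through
  h <- harmonize(ex, make_assocs("rs1", "A", "G", 0.1, 0.02, eaf = 0.2))
  expect_equal(h$beta_outcome, 0.1)
  expect_false(h$flipped)
  # swapped alleles: sign negated, EAF reflected
  h <- harmonize(ex, make_assocs("rs1", "G", "A", 0.1, 0.02, eaf = 0.8))
  expect_equal(h$beta_outcome, -0.1)
  expect_equal(h$eaf_outcome, 0.2)
  expect_true(h$flipped)
  # complement (strand flip) only: copied through
  h <- harmonize(ex, make_assocs("rs1", "T", "C", 0.1, 0.02, eaf = 0.2))
  expect_equal(h$beta_outcome, 0.1)
  expect_false(h$flipped)
  # complement + swap
  h <- harmonize(ex, make_assocs("rs1", "C", "T", 0.1, 0.02, eaf = 0.8))
  expect_equal(h$beta_outcome, -0.1)
  expect_true(h$flipped)
})

test_that("palindromic variants follow the policy", {
  ex_amb <- make_assocs("rs1", "A", "T", 0.3, 0.01, eaf = 0.50)
  out_amb <- make_assocs("rs1", "A", "T", 0.1, 0.02, eaf = 0.50)
  expect_message(h <- harmonize(ex_amb, out_amb), "ambiguous")
  expect_equal(nrow(h), 0)

  # unambiguous frequencies on the same side of 0.5: kept unflipped
  ex <- make_assocs("rs1", "A", "T", 0.3, 0.01, eaf = 0.2)
  out_same <- make_assocs("rs1", "A", "T", 0.1, 0.02, eaf = 0.25)
  h <- harmonize(ex, out_same)
  expect_equal(h$beta_outcome, 0.1)
  expect_true(h$palindromic)
  # opposite sides of 0.5: frequency-aligned by flipping
  out_opp <- make_assocs("rs1", "A", "T", 0.1, 0.02, eaf = 0.75)
  h <- harmonize(ex, out_opp)
  expect_equal(h$beta_outcome, -0.1)
  expect_equal(h$eaf_outcome, 0.25)
  # missing EAF counts as ambiguous under the default policy
  out_na <- make_assocs("rs1", "A", "T", 0.1, 0.02, eaf = NA_real_)
  expect_message(h <- harmonize(ex, out_na), "ambiguous")
  expect_equal(nrow(h), 0)
  # drop_all removes even resolvable palindromic variants
  expect_message(h <- harmonize(ex, out_same, palindromic_policy = "drop_all"),
                 "palindromic")
  expect_equal(nrow(h), 0)
  # keep retains ambiguous ones, trusting same-strand labels
  h <- harmonize(ex_amb, out_amb, palindromic_policy = "keep")
  expect_equal(h$beta_outcome, 0.1)
})

test_that("unresolvable alleles are dropped, duplicates and empty overlap error/warn", {
  ex <- make_assocs("rs1", "A", "G", 0.3, 0.01)
  expect_message(h <- harmonize(ex, make_assocs("rs1", "A", "C", 0.1, 0.02)),
                 "unresolvable")
  expect_equal(nrow(h), 0)

  dup <- make_assocs(c("rs1", "rs1"), c("A", "A"), c("G", "G"),
                     c(0.3, 0.3), c(0.01, 0.01))
  expect_error(harmonize(dup, ex), "duplicated")

  expect_warning(h <- harmonize(ex, make_assocs("rs9", "A", "G", 0.1, 0.02)),
                 "no shared")
  expect_equal(nrow(h), 0)
})

test_that("harmonize is idempotent and sign-stable on its own output", {
  set.seed(11)
  sim <- simulate_two_sample(sim_config(n_snps = 12, theta = 0.2, seed = 5,
                                        flip_fraction = 0.4,
                                        complement_fraction = 0.25))
  h1 <- harmonize(sim$exposure, sim$outcome)
  expect_true(any(h1$flipped))
  # re-harmonizing the aligned output changes nothing
  h2 <- harmonize(exposure_view(h1), outcome_view(h1))
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$beta_exposure, h1$beta_exposure)
  expect_false(any(h2$flipped))
  # and the flipped rows carry the same association as an unflipped run
  sim0 <- simulate_two_sample(sim_config(n_snps = 12, theta = 0.2, seed = 5))
  h0 <- harmonize(sim0$exposure, sim0$outcome)
  expect_equal(h1$beta_outcome[order(h1$rsid)],
               h0$beta_outcome[order(h0$rsid)])
})

test_that("orient_exposure negates the trait and is an involution", {
  a <- make_assocs("rs1", "A", "G", 0.33, 0.01, eaf = 0.3)
  expect_equal(orient_exposure(a, "increase"), a)
  d <- orient_exposure(a, "decrease")
  expect_equal(d$beta, -0.33)
  # a trait sign flip, not an allele re-encoding
  expect_equal(d$effect_allele, "A")
  expect_equal(d$eaf, 0.3)
  expect_equal(orient_exposure(d, "decrease"), a)
  # harmonized against the same outcome, the causal estimate flips sign
  out <- make_assocs("rs1", "A", "G", 0.12, 0.02, eaf = 0.3)
  h_inc <- harmonize(a, out)
  h_dec <- harmonize(d, out)
  expect_equal(h_dec$beta_outcome / h_dec$beta_exposure,
               -h_inc$beta_outcome / h_inc$beta_exposure)
})

test_that("harmonized tables serialize with the fixed column order", {
  h <- harmonize(make_assocs("rs1", "A", "G", 0.3, 0.01, eaf = 0.2),
                 make_assocs("rs1", "G", "A", 0.1, 0.02, eaf = 0.8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(header, c("rsid", "effect_allele", "other_allele",
                         "beta_exposure", "se_exposure", "beta_outcome",
                         "se_outcome", "eaf_exposure", "eaf_outcome",
                         "flipped", "palindromic"))
})
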