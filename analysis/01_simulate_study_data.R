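#!/usr/bin/env Rscript
# Generate the synthetic study datasets: summary statistics for four
# iron-status exposures (serum iron, ferritin, transferrin saturation,
# transferrin), each instrumented by three strong variants, against eleven
# liver outcomes (six continuous biomarkers, five diseases on the log-odds
# scale) plus sex-stratified disease sets and a 12-variant reverse-direction
# exposure. Every table is written as TSV under results/synthetic_study/
# together with a ground-truth JSON sidecar.
#
# Design: one exposure draw per study (as in a real two-sample setting),
# then an independent outcome draw per outcome GWAS around the true
# per-variant effects theta * beta_x.

library(ironmr)

out_dir <- "results/synthetic_study"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# Build one outcome association table around an exposure simulation's true
# instrument effects, with fresh sampling noise; the first row is emitted
# with swapped allele labels so every table exercises harmonization.
make_outcome <- function(sim, theta, se, seed, binary, n_outcome = 361194L) {
  set.seed(seed)
  tab <- sim$exposure
  m <- nrow(tab)
  tab$beta <- theta * sim$truth$beta_x_true + rnorm(m, 0, se)
  tab$se <- se
  tab$pvalue <- pvalue_two_sided(tab$beta / tab$se)
  tab$n <- n_outcome
  tab$trait_type <- if (binary) "binary" else "continuous"
  tmp <- tab$effect_allele[1]
  tab$effect_allele[1] <- tab$other_allele[1]
  tab$other_allele[1] <- tmp
  tab$beta[1] <- -tab$beta[1]
  tab$eaf[1] <- 1 - tab$eaf[1]
  tab
}

# per-exposure instrument effects (SD per allele, GIS-scale magnitudes);
# transferrin falls as iron rises, so its instrument effects are negative
exposures <- list(
  serum_iron   = list(betas = c(0.33, 0.19, 0.18), seed = 101L),
  ferritin     = list(betas = c(0.20, 0.11, 0.09), seed = 102L),
  tsat         = list(betas = c(0.45, 0.23, 0.19), seed = 103L),
  transferrin  = list(betas = c(-0.38, -0.21, -0.15), seed = 104L)
)

# true causal effects per SD increase of each exposure: biomarkers on the
# SD scale, diseases on the log-odds scale; GGT and viral hepatitis are
# simulated null. Transferrin's harmful direction is decreasing, so its
# true effects carry the opposite sign.
biomarkers <- c(ALP = 0.60, ALT = 0.40, AST = 0.45, GGT = 0,
                DBIL = 0.10, TBIL = 0.50)
diseases <- c(NAFLD = log(1.9), ALD = log(1.75),
              fibrosis_cirrhosis = log(1.5), viral_hepatitis = 0,
              liver_malignancy = log(1.3))
strata_diseases <- c("NAFLD", "fibrosis_cirrhosis", "viral_hepatitis")

se_biomarker <- 0.05
se_disease <- 0.25   # log-odds SEs are large: few cases per cohort

truth <- list()
noise_seed <- 1000L
for (ex_name in names(exposures)) {
  ex <- exposures[[ex_name]]
  sim <- simulate_two_sample(sim_config(
    n_snps = 3, theta = 0, instrument_betas = ex$betas,
    se_exposure = c(0.016, 0.012, 0.008), seed = ex$seed))
  write_summary_stats(sim$exposure,
                      file.path(out_dir, paste0("exposure_", ex_name,
                                                ".tsv")))
  sign_dir <- if (ex_name == "transferrin") -1 else 1
  outcome_thetas <- c(
    biomarkers * sign_dir,
    diseases * sign_dir,
    # sex strata: the simulated hepatotoxic effect is confined to men
    setNames(diseases[strata_diseases] * sign_dir,
             paste0(strata_diseases, "_male")),
    setNames(rep(0, length(strata_diseases)),
             paste0(strata_diseases, "_female"))
  )
  for (out_name in names(outcome_thetas)) {
    noise_seed <- noise_seed + 1L
    binary <- !(out_name %in% names(biomarkers))
    tab <- make_outcome(sim, outcome_thetas[[out_name]],
                        if (binary) se_disease else se_biomarker,
                        seed = noise_seed, binary = binary)
    write_summary_stats(tab,
                        file.path(out_dir, paste0("outcome_", ex_name, "_",
                                                  out_name, ".tsv")))
    truth[[paste(ex_name, out_name, sep = " -> ")]] <-
      list(theta = outcome_thetas[[out_name]], noise_seed = noise_seed)
  }
}

# reverse direction: a 12-variant liability exposure (NAFLD-style) with no
# causal effect on any iron indicator
rev_sim <- simulate_two_sample(sim_config(
  n_snps = 12, theta = 0, beta_range = c(0.08, 0.25),
  se_exposure = 0.02, se_outcome = 0.01, seed = 500L))
write_summary_stats(rev_sim$exposure,
                    file.path(out_dir, "reverse_exposure_nafld.tsv"))
rev_truth <- list()
for (iron in names(exposures)) {
  noise_seed <- noise_seed + 1L
  tab <- make_outcome(rev_sim, theta = 0, se = 0.01, seed = noise_seed,
                      binary = FALSE, n_outcome = 48972L)
  write_summary_stats(tab, file.path(out_dir,
                                     paste0("reverse_outcome_", iron,
                                            ".tsv")))
  rev_truth[[iron]] <- list(theta = 0, noise_seed = noise_seed)
}

if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(list(forward = truth, reverse = rev_truth),
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
}

cat("Wrote", length(list.files(out_dir)), "files to", out_dir, "\n")
cat("Forward grid: 4 exposures x", length(biomarkers) + length(diseases),
    "pooled outcomes +", 2 * length(strata_diseases),
    "sex-stratified disease sets per exposure; reverse: one 12-variant",
    "exposure x 4 iron indicators, simulated null.\n")
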