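#!/usr/bin/env Rscript
# Run the forward MR grid on the synthetic study data: four iron-status
# exposures against all liver outcomes (pooled and sex-stratified), with
# fixed-effect IVW as the main analysis and weighted-median / MR-Egger as
# sensitivity analyses. Writes results/forward_grid.tsv and .md.
#
# Run analysis/01_simulate_study_data.R first.

library(ironmr)

data_dir <- "results/synthetic_study"
stopifnot(dir.exists(data_dir))

binary_outcomes <- c("NAFLD", "ALD", "fibrosis_cirrhosis",
                     "viral_hepatitis", "liver_malignancy")
is_binary <- function(nm) sub("_(male|female)$", "", nm) %in% binary_outcomes
stratum_of <- function(nm) {
  if (grepl("_male$", nm)) "male" else if (grepl("_female$", nm)) "female"
  else "all"
}

# weighted-median bootstrap kept at 2000 draws per cell: SE Monte-Carlo
# noise is ~2% of the SE there, well below anything the grid reports at
all_rows <- list()
for (ex_name in c("serum_iron", "ferritin", "tsat", "transferrin")) {
  exposure_path <- file.path(data_dir, paste0("exposure_", ex_name, ".tsv"))
  outcome_files <- list.files(
    data_dir, pattern = paste0("^outcome_", ex_name, "_"), full.names = TRUE)
  outcomes <- list()
  for (f in outcome_files) {
    nm <- sub(paste0("^outcome_", ex_name, "_(.*)\\.tsv$"), "\\1",
              basename(f))
    outcomes[[nm]] <- list(
      path = f,
      trait_type = if (is_binary(nm)) "binary" else "continuous",
      stratum = stratum_of(nm))
  }
  cfg <- study_config(
    exposures = setNames(list(list(
      path = exposure_path,
      # transferrin effects are expressed per SD decrease so that all four
      # indicators point in the iron-raising direction
      direction = if (ex_name == "transferrin") "decrease" else "increase")),
      ex_name),
    outcomes = outcomes,
    methods = c("ivw_fixed", "weighted_median", "mr_egger"),
    n_boot = 2000L, seed = 20260101L)
  all_rows[[ex_name]] <- run_study(cfg)
}
rows <- do.call(rbind, all_rows)
rownames(rows) <- NULL

render_report(rows, "tsv", path = "results/forward_grid.tsv")
render_report(rows, "markdown", path = "results/forward_grid.md")

ivw <- rows[rows$method == "ivw_fixed" & rows$stratum == "all", ]
cat(nrow(rows), "result rows;", nrow(ivw), "pooled IVW cells, of which",
    sum(ivw$significant_nominal), "are nominally significant at P < 0.05.\n")
cat("Pooled IVW odds ratios for the simulated diseases (per SD of",
    "iron-raising exposure):\n")
dz <- ivw[!is.na(ivw$or), ]
for (i in seq_len(nrow(dz))) {
  cat(sprintf("  %-12s -> %-18s OR %.2f (%.2f-%.2f), P = %.3g\n",
              dz$exposure[i], dz$outcome[i], dz$or[i], dz$or_ci_low[i],
              dz$or_ci_high[i], dz$pvalue[i]))
}
cat("Wrote results/forward_grid.tsv and results/forward_grid.md\n")
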