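#!/usr/bin/env Rscript
# Reverse-direction MR on the synthetic data: the 12-variant liability
# exposure against the four iron-status indicators, all simulated with no
# causal effect. Writes results/reverse_grid.tsv.
#
# Run analysis/01_simulate_study_data.R first.

library(ironmr)

data_dir <- "results/synthetic_study"
stopifnot(dir.exists(data_dir))

outcomes <- list()
for (iron in c("serum_iron", "ferritin", "tsat", "transferrin")) {
  outcomes[[iron]] <- list(
    path = file.path(data_dir, paste0("reverse_outcome_", iron, ".tsv")))
}
cfg <- study_config(
  exposures = list(nafld_liability = list(
    path = file.path(data_dir, "reverse_exposure_nafld.tsv"))),
  outcomes = outcomes,
  methods = c("ivw_fixed", "weighted_median", "mr_egger"),
  n_boot = 2000L, seed = 20260102L)
rows <- run_reverse(cfg)

render_report(rows, "tsv", path = "results/reverse_grid.tsv")

ivw <- rows[rows$method == "ivw_fixed", ]
cat("Reverse MR, 12 instruments per cell (n_snps =",
    paste(unique(ivw$n_snps), collapse = ","), "):\n")
for (i in seq_len(nrow(ivw))) {
  cat(sprintf("  liability -> %-12s theta %+.3f (%.3f), P = %.3f%s\n",
              ivw$outcome[i], ivw$theta[i], ivw$se[i], ivw$pvalue[i],
              if (ivw$significant_nominal[i]) "  *nominal*" else ""))
}
cat("All cells were simulated under the null; nominal hits are expected",
    "at roughly the 5% rate.\n")
cat("Wrote results/reverse_grid.tsv\n")
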