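#!/usr/bin/env Rscript
# Analytic power for the study design: continuous liver biomarkers
# (n = 361,194) and rare binary liver diseases at realistic case fractions,
# over a range of hypothesized effects, with instruments explaining ~3% of
# exposure variance (three strong variants). Writes results/power_table.tsv.

library(ironmr)

r2_gx <- 0.03
n_cont <- 361194

grid_cont <- expand.grid(beta = c(0.05, 0.1, 0.2, 0.4, 0.6))
grid_cont$outcome_type <- "continuous"
grid_cont$n <- n_cont
grid_cont$case_fraction <- NA
grid_cont$power <- vapply(grid_cont$beta, function(b)
  mr_power_continuous(n_cont, r2_gx, b), numeric(1))

# case fractions span NAFLD-like (~0.5%) to common-disease (~5%) outcomes
grid_bin <- expand.grid(or = c(1.2, 1.5, 1.9, 3),
                        case_fraction = c(0.005, 0.01, 0.05))
grid_bin$outcome_type <- "binary"
grid_bin$n <- n_cont
grid_bin$power <- mapply(function(o, k)
  mr_power_binary(n_cont, r2_gx, o, k), grid_bin$or, grid_bin$case_fraction)

tab <- rbind(
  data.frame(outcome_type = grid_cont$outcome_type, n = grid_cont$n,
             effect = grid_cont$beta, case_fraction = NA,
             power = grid_cont$power),
  data.frame(outcome_type = grid_bin$outcome_type, n = grid_bin$n,
             effect = grid_bin$or, case_fraction = grid_bin$case_fraction,
             power = grid_bin$power)
)
dir.create("results", showWarnings = FALSE)
utils::write.table(tab, "results/power_table.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Power at alpha 0.05, r2 =", r2_gx, ", n =", n_cont, ":\n")
cat(sprintf("  continuous beta 0.1: %.3f\n",
            mr_power_continuous(n_cont, r2_gx, 0.1)))
cat(sprintf("  binary OR 1.9 at 0.5%% cases: %.3f\n",
            mr_power_binary(n_cont, r2_gx, 1.9, 0.005)))
cat(sprintf("  binary OR 1.2 at 0.5%% cases: %.3f",
            mr_power_binary(n_cont, r2_gx, 1.2, 0.005)),
    "- modest effects on rare diseases are underpowered;\n")
cat("  null findings on rare outcomes therefore do not exclude moderate",
    "effects.\n")
cat("Wrote results/power_table.tsv\n")
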