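#!/usr/bin/env Rscript
# Apply the five-step threshold decision tree with the default national
# thresholds, after the coverage filter, and write per-nutrient strategy
# assignments.

library(nutprior)

res <- run_pipeline("results/synthetic/metrics.csv",
                    fluxes = "results/synthetic/fluxes.csv",
                    thresholds = threshold_set(), min_pct_land = 1.5,
                    out_dir = "results/classified")

asg <- res$assignments
for (nu in c("N", "P")) {
  a <- asg[asg$nutrient == nu, ]
  pri <- sum(a$priority, na.rm = TRUE)
  message(nu, ": ", pri, " of ", nrow(a), " subwatersheds high-surplus (",
          percent_share(pri, nrow(a)), "%); ",
          sum(a$input_reduction), " on the in-field branch (",
          percent_share(sum(a$input_reduction), pri), "% of priority)")
}
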