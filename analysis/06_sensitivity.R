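#!/usr/bin/env Rscript
# How class counts respond to threshold choice: sweep the surplus and
# efficiency cutoffs around their defaults.

library(nutprior)

metrics <- read_metrics("results/classified/metrics_filtered.csv")

scan <- sensitivity_scan(metrics, list(
  surplus_n = c(3.5, 7, 14),
  efficiency = c(0.5, 0.7, 0.75)
), nutrients = "N")

readr::write_csv(scan, "results/sensitivity_n.csv", na = "")
message("priority count by N-surplus cutoff (at efficiency 0.7):")
sub <- scan[scan$efficiency == 0.7, ]
for (i in order(sub$surplus_n)) {
  message("  >= ", sub$surplus_n[i], " kg-N/ha/yr: ", sub$n_priority[i],
          " subwatersheds, ", sub$n_input_reduction[i], " in-field branch")
}
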