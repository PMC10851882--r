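#!/usr/bin/env Rscript
# National and basin-level reporting products: strategy tallies,
# net-surplus shares of the prioritized sets, the Spearman matrix of
# area-based metrics, and median/IQR summaries of percent metrics.

library(nutprior)

metrics <- read_metrics("results/classified/metrics_filtered.csv")
asg <- readr::read_csv("results/classified/strategies.csv",
                       col_types = readr::cols(
                         watershed_id = readr::col_character(),
                         nutrient = readr::col_character(),
                         missing_reason = readr::col_character(),
                         strategy_class = readr::col_character(),
                         .default = readr::col_logical()
                       ))

for (nu in c("N", "P")) {
  message("net CONUS ", nu, " surplus in priority subwatersheds: ",
          round(net_surplus_share(metrics, asg, nu), 1), "%")
}

agg <- tally_aggregates(asg, group_by = "CONUS")
readr::write_csv(tally(asg), "results/tally.csv", na = "")
readr::write_csv(agg, "results/tally_aggregates.csv", na = "")

sm <- spearman_matrix(metrics, c("ag_area_km2", "pasture_area_km2",
                                 "tile_area_km2", "nonbuffered_area_km2",
                                 "prw_area_km2", "n_surplus", "p_surplus"))
readr::write_csv(tibble::as_tibble(sm$rho, rownames = "metric"),
                 "results/correlations.csv", na = "")
message("Spearman(nonbuffered area, agricultural area) = ",
        round(sm$rho["nonbuffered_area_km2", "ag_area_km2"], 2))

bs <- basin_summary(metrics, c("pct_tile_of_ag", "pct_nonbuffered_ws",
                               "pct_prw_of_ag", "pct_ag", "nue", "pue"))
readr::write_csv(bs, "results/basin_summary.csv", na = "")
message("basin summary rows: ", nrow(bs))
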