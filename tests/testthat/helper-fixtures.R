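# Shared fixtures and independent oracles, built in code at test time.

# Random but valid flux records (P records carry no fixation/deposition).
random_fluxes <- function(n, seed = 1) {
  set.seed(seed)
  nutrient <- sample(c("N", "P"), n, replace = TRUE)
  is_n <- nutrient == "N"
  tibble::tibble(
    watershed_id = sprintf("%08d", seq_len(n)),
    nutrient = nutrient,
    year = 2012L,
    fertilizer_kg = runif(n, 0, 1e6),
    fixation_kg = ifelse(is_n, runif(n, 0, 4e5), 0),
    deposition_kg = ifelse(is_n, runif(n, 0, 1e5), 0),
    livestock_kg = runif(n, 0, 6e5),
    crop_removal_kg = runif(n, 0, 1.5e6),
    watershed_area_ha = runif(n, 1e3, 1e6)
  )
}

# One-row metrics record with friendly defaults; override any field.
metrics_row <- function(watershed_id = "07080105", n_surplus = 10,
                        p_surplus = 2, nue = 0.5, pue = 0.5,
                        pct_tile_of_ag = 5, pct_nonbuffered_ws = 1,
                        pct_prw_of_ag = 20, area_km2 = 1000,
                        pct_land = 100) {
  tibble::tibble(
    watershed_id = watershed_id, basin_id = substr(watershed_id, 1, 2),
    area_km2 = area_km2, pct_land = pct_land, pct_cropland = 20,
    pct_pasture = 10, pct_ag = 30, n_surplus = n_surplus,
    p_surplus = p_surplus, nue = nue, pue = pue,
    pct_tile_of_ag = pct_tile_of_ag,
    pct_nonbuffered_ws = pct_nonbuffered_ws,
    pct_prw_of_ag = pct_prw_of_ag
  )
}

# Independent scalar hand-trace of the five-step decision tree, written as
# plain nested if/else so it shares no code with the vectorized
# implementation.
oracle_classify_one <- function(m, thr, nutrient) {
  surplus <- if (nutrient == "N") m$n_surplus else m$p_surplus
  eff <- if (nutrient == "N") m$nue else m$pue
  s_thr <- if (nutrient == "N") thr$surplus_n else thr$surplus_p
  if (is.na(surplus)) return("UNCLASSIFIED_MISSING")
  if (surplus < s_thr) return("NOT_PRIORITY")
  if (is.na(eff) || is.na(m$pct_tile_of_ag) || is.na(m$pct_nonbuffered_ws)) {
    return("UNCLASSIFIED_MISSING")
  }
  infield <- eff < thr$efficiency
  drain <- m$pct_tile_of_ag >= thr$tile_pct
  buff <- m$pct_nonbuffered_ws >= thr$nonbuffered_pct
  if (!drain && !buff) return("INFIELD_ONLY")
  if (is.na(m$pct_prw_of_ag)) return("UNCLASSIFIED_MISSING")
  wet <- m$pct_prw_of_ag >= thr$prw_pct
  stem <- if (wet) "WETLAND" else "BUFFER"
  if (drain) stem <- paste0(stem, "_DRAINAGE")
  paste0(if (infield) "INFIELD_" else "EDGE_", stem)
}

# Brute-force block means for grid coarsening.
oracle_coarsen <- function(grid, f) {
  nr <- ceiling(nrow(grid) / f) * f
  nc <- ceiling(ncol(grid) / f) * f
  g <- matrix(0, nr, nc)
  g[seq_len(nrow(grid)), seq_len(ncol(grid))] <- grid
  out <- matrix(NA_real_, nr / f, nc / f)
  for (i in seq_len(nr / f)) {
    for (j in seq_len(nc / f)) {
      out[i, j] <- mean(g[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
    }
  }
  out
}

# Per-cell tally for zonal percentages.
oracle_zonal <- function(tile, ag, zones, cell_area_m2) {
  ids <- sort(unique(as.character(zones[!is.na(zones)])))
  do.call(rbind, lapply(ids, function(id) {
    sel <- !is.na(zones) & zones == id
    ts <- 0
    as_ <- 0
    for (k in which(sel)) {
      ts <- ts + tile[k]
      as_ <- as_ + ag[k]
    }
    data.frame(watershed_id = id,
               tile_area_km2 = ts * cell_area_m2 / 1e6,
               ag_area_km2 = as_ * cell_area_m2 / 1e6,
               pct = if (as_ > 0) 100 * ts / as_ else NA_real_)
  }))
}

# Average-rank Spearman by explicit rank-then-Pearson with pairwise
# deletion, independent of stats::cor(method = "spearman").
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# The published pairwise Spearman correlations (§-level values reported for
# the national HUC8 data), as (metric, metric, rho) triples.
published_spearman_pairs <- function() {
  tribble_vals <- list(
    c("n_surplus", "ag_area", 0.68),
    c("p_surplus", "pasture_area", 0.36),
    c("n_surplus", "p_surplus", 0.65),
    c("nue", "pue", 0.91),
    c("pue", "p_surplus", -0.36),
    c("nue", "n_surplus", 0.10),
    c("tile_area", "ag_area", 0.73),
    c("tile_area", "n_surplus", 0.62),
    c("tile_area", "p_surplus", 0.25),
    c("nonbuffered_area", "ag_area", 0.91),
    c("nonbuffered_area", "n_surplus", 0.62),
    c("nonbuffered_area", "tile_area", 0.72),
    c("prw_area", "ag_area", 0.80),
    c("prw_area", "tile_area", 0.69),
    c("prw_area", "nonbuffered_area", 0.79),
    c("prw_area", "n_surplus", 0.55)
  )
  data.frame(
    a = vapply(tribble_vals, `[`, "", 1),
    b = vapply(tribble_vals, `[`, "", 2),
    rho = as.numeric(vapply(tribble_vals, `[`, "", 3))
  )
}

# Map copula metric names to metrics-table columns.
sim_metric_columns <- c(
  ag_area = "ag_area_km2", pasture_area = "pasture_area_km2",
  n_surplus = "n_surplus", p_surplus = "p_surplus", nue = "nue", pue = "pue",
  tile_area = "tile_area_km2", nonbuffered_area = "nonbuffered_area_km2",
  prw_area = "prw_area_km2"
)
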