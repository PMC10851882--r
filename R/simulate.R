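#' Seeded synthetic subwatershed tables
#'
#' A Gaussian copula reproduces the published pairwise Spearman
#' rank-correlation structure among the area-based metrics (agricultural,
#' pasture, tile-drained, nonbuffered and restorable-wetland areas),
#' surpluses and efficiencies; marginal families are chosen so the
#' published quantile anchors hold approximately (median N surplus 7 and P
#' surplus 1 kg ha^-1 yr^-1, efficiency ~75th percentile near 0.7, percent
#' tile of agricultural land ~95th percentile near 30%, nonbuffered ~40th
#' percentile near 2% of the watershed, restorable wetlands median near 10%
#' of agricultural land). Percent metrics are derived from the simulated
#' areas. Watershed ids are labels only: no spatial contiguity is
#' simulated.
#'
#' @name synthetic
NULL

.sim_metrics <- c("ag_area", "pasture_area", "n_surplus", "p_surplus",
                  "nue", "pue", "tile_area", "nonbuffered_area", "prw_area")

#' Default pairwise Spearman targets
#'
#' Published CONUS HUC8 rank correlations; unspecified pairs default to 0
#' in the latent space (before positive-definiteness repair).
#'
#' @return A symmetric 9x9 matrix with unit diagonal over
#'   `ag_area`, `pasture_area`, `n_surplus`, `p_surplus`, `nue`, `pue`,
#'   `tile_area`, `nonbuffered_area`, `prw_area`.
#' @export
default_spearman_targets <- function() {
  m <- diag(length(.sim_metrics))
  dimnames(m) <- list(.sim_metrics, .sim_metrics)
  set <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  set("n_surplus", "ag_area", 0.68)
  set("p_surplus", "pasture_area", 0.36)
  set("n_surplus", "p_surplus", 0.65)
  set("nue", "pue", 0.91)
  set("pue", "p_surplus", -0.36)
  set("nue", "n_surplus", 0.10)
  set("tile_area", "ag_area", 0.73)
  set("tile_area", "n_surplus", 0.62)
  set("tile_area", "p_surplus", 0.25)
  set("nonbuffered_area", "ag_area", 0.91)
  set("nonbuffered_area", "n_surplus", 0.62)
  set("nonbuffered_area", "tile_area", 0.72)
  set("prw_area", "ag_area", 0.80)
  set("prw_area", "tile_area", 0.69)
  set("prw_area", "nonbuffered_area", 0.79)
  set("prw_area", "n_surplus", 0.55)
  # pasture is a subset of agricultural land, so independence from ag_area
  # is unphysical; a moderate positive default keeps the derived cropland
  # area non-negative without distorting the published pairs
  set("pasture_area", "ag_area", 0.60)
  attr(m, "specified") <- !is.na(m) & (m != 0 | row(m) == col(m))
  m
}

#' Default marginal specifications
#'
#' Families: `lnorm` (areas, km^2), `shlnorm` (shifted lognormal for
#' surpluses, so soil-mining negatives occur), `logitnorm` (efficiencies,
#' bounded in (0, 1)). Parameters were calibrated against the published
#' quantile anchors and national area totals; see the methods vignette.
#'
#' @return Named list of marginal specs.
#' @export
default_marginals <- function() {
  list(
    ag_area = list(family = "lnorm", meanlog = log(540), sdlog = 1.9),
    pasture_area = list(family = "lnorm", meanlog = log(100), sdlog = 1.5),
    n_surplus = list(family = "shlnorm", meanlog = log(12), sdlog = 0.868,
                     shift = 5),
    p_surplus = list(family = "shlnorm", meanlog = log(2.2), sdlog = 0.473,
                     shift = 1.2),
    nue = list(family = "logitnorm", mu = stats::qlogis(0.46), sigma = 1.155),
    pue = list(family = "logitnorm", mu = stats::qlogis(0.41), sigma = 1.939),
    tile_area = list(family = "lnorm", meanlog = log(17.6), sdlog = 1.9),
    nonbuffered_area = list(family = "lnorm", meanlog = log(98.5), sdlog = 1.6),
    prw_area = list(family = "lnorm", meanlog = log(54), sdlog = 1.7),
    # not part of the copula: percent agriculture of the watershed,
    # median 16% with IQR spanning roughly 3-41%
    pct_ag = list(family = "logitnorm", mu = stats::qlogis(0.16), sigma = 1.918)
  )
}

#' Marginal quantile function
#' @noRd
.q_marginal <- function(u, spec) {
  switch(spec$family,
    lnorm = stats::qlnorm(u, spec$meanlog, spec$sdlog),
    shlnorm = stats::qlnorm(u, spec$meanlog, spec$sdlog) - spec$shift,
    logitnorm = stats::plogis(stats::qnorm(u, spec$mu, spec$sigma)),
    stop("unknown marginal family: ", spec$family, call. = FALSE)
  )
}

#' Convert a Spearman correlation to the latent Pearson correlation
#'
#' For a Gaussian copula the latent Pearson correlation producing a given
#' Spearman rho is `2 * sin(pi * rho / 6)`.
#'
#' @param rho_s Spearman correlation(s) in [-1, 1].
#' @return Pearson correlation(s).
#' @export
spearman_to_pearson <- function(rho_s) {
  if (any(abs(rho_s) > 1, na.rm = TRUE)) {
    stop("Spearman correlation must be in [-1, 1]", call. = FALSE)
  }
  2 * sin(pi * rho_s / 6)
}

#' Build a simulation configuration
#'
#' Defaults are the national study conditions: 2092 subwatersheds across
#' 18 river basins.
#'
#' @param n_watersheds Number of subwatersheds (>= 10).
#' @param n_basins Number of HUC2 basins to allocate ids over.
#' @param seed Integer seed; every random draw is governed by it.
#' @param target_spearman Symmetric Spearman target matrix (see
#'   [default_spearman_targets()]).
#' @param marginals Marginal specs (see [default_marginals()]).
#' @param basin_alpha Dirichlet concentration for uneven basin sizes.
#' @param coastal_frac Fraction of records given a low percent-land value
#'   (emulating coastal subwatersheds caught by the coverage filter).
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_watersheds = 2092, n_basins = 18, seed = 42,
                              target_spearman = default_spearman_targets(),
                              marginals = default_marginals(),
                              basin_alpha = 1.2, coastal_frac = 0.02) {
  if (n_watersheds < 10) stop("n_watersheds must be >= 10", call. = FALSE)
  if (!isSymmetric(unname(target_spearman)) ||
      any(abs(diag(target_spearman) - 1) > 1e-12)) {
    stop("target_spearman must be symmetric with unit diagonal", call. = FALSE)
  }
  structure(
    list(n_watersheds = as.integer(n_watersheds),
         n_basins = as.integer(n_basins), seed = as.integer(seed),
         target_spearman = target_spearman, marginals = marginals,
         basin_alpha = basin_alpha, coastal_frac = coastal_frac),
    class = "simulation_config"
  )
}

#' Latent correlation matrix: convert and repair to positive definite
#' @noRd
.latent_corr_cache <- new.env(parent = emptyenv())

.latent_corr <- function(target_spearman) {
  key <- paste(signif(as.numeric(target_spearman), 12), collapse = ",")
  hit <- .latent_corr_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .latent_corr_impl(target_spearman)
  .latent_corr_cache[[key]] <- out
  out
}

.latent_corr_impl <- function(target_spearman) {
  p <- spearman_to_pearson(target_spearman)
  diag(p) <- 1
  spec <- attr(target_spearman, "specified")
  if (is.null(spec)) spec <- target_spearman != 0 | diag(nrow(p)) == 1
  min_eig <- function(m) {
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (min_eig(p) < 1e-8) {
    # The published pairwise correlations need not form a consistent
    # matrix. Alternate projection onto the PD cone (Higham, via
    # Matrix::nearPD) and onto the set of matrices with the published
    # entries held exact; only the unspecified entries move.
    fixed <- p
    for (i in seq_len(400)) {
      p <- as.matrix(Matrix::nearPD(p, corr = TRUE, keepDiag = TRUE)$mat)
      p[spec] <- fixed[spec]
      if (min_eig(p) > 1e-8) break
    }
    # completions can sit on the PSD boundary; a negligible ridge keeps
    # the Cholesky factor stable without visibly moving any entry
    eps <- 1e-6
    p <- (p + eps * diag(nrow(p))) / (1 + eps)
    diag(p) <- 1
    if (min_eig(p) <= 0) {
      off <- abs(p - fixed)
      off[!spec] <- 0
      diag(off) <- 0
      worst <- which(off == max(off), arr.ind = TRUE)[1, ]
      stop("correlation targets admit no positive-definite completion; ",
           "most strained pair: ", rownames(fixed)[worst[1]], " ~ ",
           colnames(fixed)[worst[2]], call. = FALSE)
    }
  }
  dimnames(p) <- dimnames(target_spearman)
  p
}

#' Simulate a synthetic subwatershed metrics table
#'
#' Draws a latent multivariate normal with the repaired latent correlation,
#' maps each column through its marginal quantile function, derives the
#' percent metrics from areas, and allocates watershed ids over unevenly
#' sized basins. Identical `(config, seed)` give identical tables.
#'
#' Small consistency clips keep derived quantities physical (pasture, tile,
#' nonbuffered and wetland areas cannot exceed agricultural area).
#'
#' @param cfg A [simulation_config()].
#' @return A tibble with id columns, area columns (km^2), surpluses
#'   (kg ha^-1 yr^-1), efficiencies, and the derived percent metrics.
#' @export
simulate_metrics <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_watersheds
  k <- length(.sim_metrics)
  set.seed(cfg$seed)

  R <- .latent_corr(cfg$target_spearman[.sim_metrics, .sim_metrics])
  z <- matrix(stats::rnorm(n * k), n, k) %*% chol(R)
  u <- stats::pnorm(z)
  colnames(u) <- .sim_metrics
  vals <- lapply(.sim_metrics, function(mname) {
    .q_marginal(u[, mname], cfg$marginals[[mname]])
  })
  names(vals) <- .sim_metrics
  m <- tibble::as_tibble(vals)

  # physical consistency: sub-areas cannot exceed agricultural area
  m$pasture_area <- pmin(m$pasture_area, 0.9 * m$ag_area)
  m$tile_area <- pmin(m$tile_area, m$ag_area)
  m$nonbuffered_area <- pmin(m$nonbuffered_area, m$ag_area)
  m$prw_area <- pmin(m$prw_area, m$ag_area)

  pct_ag <- 100 * .q_marginal(stats::runif(n), cfg$marginals$pct_ag)
  area_km2 <- m$ag_area / (pct_ag / 100)
  coastal <- stats::runif(n) < cfg$coastal_frac
  pct_land <- ifelse(coastal, stats::runif(n, 0, 5), 100)

  # uneven basin sizes via a Dirichlet weight vector
  w <- stats::rgamma(cfg$n_basins, shape = cfg$basin_alpha)
  basin <- sample.int(cfg$n_basins, n, replace = TRUE, prob = w / sum(w))
  ord <- order(basin)
  idx <- stats::ave(basin[ord], basin[ord], FUN = seq_along)
  watershed_id <- character(n)
  watershed_id[ord] <- sprintf("%02d%06d", basin[ord], idx)

  tibble::tibble(
    watershed_id = watershed_id,
    basin_id = substr(watershed_id, 1, 2),
    area_km2 = area_km2,
    pct_land = pct_land,
    pct_cropland = 100 * ((m$ag_area - m$pasture_area) / area_km2),
    pct_pasture = 100 * (m$pasture_area / area_km2),
    pct_ag = pct_ag,
    n_surplus = m$n_surplus,
    p_surplus = m$p_surplus,
    nue = m$nue,
    pue = m$pue,
    # ratio first so saturated cells give exactly 100
    pct_tile_of_ag = 100 * (m$tile_area / m$ag_area),
    pct_nonbuffered_ws = 100 * (m$nonbuffered_area / area_km2),
    pct_prw_of_ag = 100 * (m$prw_area / m$ag_area),
    ag_area_km2 = m$ag_area,
    pasture_area_km2 = m$pasture_area,
    tile_area_km2 = m$tile_area,
    nonbuffered_area_km2 = m$nonbuffered_area,
    prw_area_km2 = m$prw_area
  )
}

#' Reconcile efficiency with the sign of the surplus
#'
#' In a closed budget, efficiency below 1 implies a positive surplus and
#' vice versa. The copula draws efficiencies and surpluses as separate
#' marginals, so a small fraction of rows violate that accounting link;
#' this helper mirrors the efficiency across 1 (`e -> 2 - e`) on those
#' rows, preserving its distance from break-even. Needed before inverting
#' metrics to component fluxes.
#'
#' @param metrics A metrics table.
#' @return The table with `nue`/`pue` adjusted where sign-inconsistent.
#' @export
reconcile_efficiency <- function(metrics) {
  fix <- function(e, s) {
    bad <- (s > 0 & e >= 1) | (s < 0 & e <= 1)
    bad[is.na(bad)] <- FALSE
    e[bad] <- 2 - e[bad]
    e
  }
  metrics$nue <- fix(metrics$nue, metrics$n_surplus)
  metrics$pue <- fix(metrics$pue, metrics$p_surplus)
  metrics
}

#' Invert metrics to component flux tables
#'
#' For each watershed and nutrient, total inputs follow from the budget
#' identity `surplus * area = inputs * (1 - efficiency)`; outputs are
#' `efficiency * inputs`. Inputs are split into components (fertilizer,
#' fixation, deposition, livestock for N; fertilizer, livestock for P) with
#' year-to-year jitter around configured proportions, while totals — hence
#' surplus and efficiency — stay exact each year.
#'
#' @param metrics Metrics table (surpluses, efficiencies, `area_km2`).
#' @param seed Integer seed for the component-split jitter.
#' @param years Census years to emit one record per.
#' @param n_split,p_split Mean input proportions (N: fertilizer, fixation,
#'   deposition, livestock; P: fertilizer, livestock).
#' @param on_incompatible What to do with rows whose efficiency is on the
#'   wrong side of 1 for their surplus sign: `"error"` (default) or
#'   `"drop"` (with a warning). Use [reconcile_efficiency()] upstream to
#'   avoid both.
#' @return A flux tibble in the [validate_fluxes()] schema.
#' @export
simulate_fluxes <- function(metrics, seed = 1,
                            years = c(2002, 2007, 2012),
                            n_split = c(fertilizer = 0.55, fixation = 0.20,
                                        deposition = 0.05, livestock = 0.20),
                            p_split = c(fertilizer = 0.60, livestock = 0.40),
                            on_incompatible = c("error", "drop")) {
  on_incompatible <- match.arg(on_incompatible)
  set.seed(seed)
  long <- dplyr::bind_rows(
    tibble::tibble(watershed_id = metrics$watershed_id, nutrient = "N",
                   surplus = metrics$n_surplus, efficiency = metrics$nue,
                   area_ha = metrics$area_km2 * 100),
    tibble::tibble(watershed_id = metrics$watershed_id, nutrient = "P",
                   surplus = metrics$p_surplus, efficiency = metrics$pue,
                   area_ha = metrics$area_km2 * 100)
  )
  bad <- (long$surplus > 0 & long$efficiency >= 1) |
         (long$surplus < 0 & long$efficiency <= 1)
  if (any(bad)) {
    msg <- paste0(sum(bad), " row(s) with efficiency inconsistent with the ",
                  "surplus sign (e.g. efficiency < 1 with negative surplus)")
    if (on_incompatible == "error") stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    long <- long[!bad, ]
  }
  near_one <- abs(long$efficiency - 1) < 1e-12
  inputs <- ifelse(near_one, 10 * long$area_ha,
                   long$surplus * long$area_ha / (1 - long$efficiency))
  outputs <- ifelse(near_one, inputs, long$efficiency * inputs)

  rows <- lapply(years, function(yr) {
    is_n <- long$nutrient == "N"
    split_one <- function(mean_split, m) {
      # jittered Dirichlet around the mean proportions, concentration 200
      g <- matrix(stats::rgamma(m * length(mean_split),
                                shape = 200 * rep(mean_split, each = m)),
                  m, length(mean_split))
      g / rowSums(g)
    }
    ns <- split_one(n_split, sum(is_n))
    ps <- split_one(p_split, sum(!is_n))
    fert <- fix <- dep <- liv <- numeric(nrow(long))
    fert[is_n] <- ns[, 1] * inputs[is_n]
    fix[is_n] <- ns[, 2] * inputs[is_n]
    dep[is_n] <- ns[, 3] * inputs[is_n]
    liv[is_n] <- ns[, 4] * inputs[is_n]
    fert[!is_n] <- ps[, 1] * inputs[!is_n]
    liv[!is_n] <- ps[, 2] * inputs[!is_n]
    tibble::tibble(
      watershed_id = long$watershed_id, nutrient = long$nutrient, year = yr,
      fertilizer_kg = fert, fixation_kg = fix, deposition_kg = dep,
      livestock_kg = liv, crop_removal_kg = outputs,
      watershed_area_ha = long$area_ha
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$watershed_id, .data$nutrient,
                 .data$year)
}

#' Simulate a toy raster stack with known zonal tile fractions
#'
#' Builds a zone grid of horizontal bands (one per target), scatters an
#' agricultural mask within each zone, and places tile cells inside the
#' mask so that each zone's percent tile of agricultural land recovers its
#' target up to one-cell rounding.
#'
#' @param targets Named numeric vector of per-zone tile fractions of
#'   agricultural land, each in [0, 1]; names become zone ids (defaults to
#'   zero-padded codes).
#' @param cells_per_zone Cells in each zone band (a multiple of `ncol`).
#' @param ncol Grid width in cells.
#' @param ag_fraction Fraction of each zone's cells that are agricultural.
#' @param cell_area_m2 Cell area (default a 150 m cell).
#' @param seed Integer seed.
#' @return A list with `tile`, `ag` (0/1 matrices), `zones` (character
#'   matrix) and `cell_area_m2`.
#' @export
simulate_rasters <- function(targets, cells_per_zone = 400, ncol = 20,
                             ag_fraction = 0.6, cell_area_m2 = 150^2,
                             seed = 1) {
  if (any(targets < 0 | targets > 1)) {
    stop("targets must be fractions in [0, 1]", call. = FALSE)
  }
  if (cells_per_zone %% ncol != 0) {
    stop("cells_per_zone must be a multiple of ncol", call. = FALSE)
  }
  set.seed(seed)
  nz <- length(targets)
  ids <- names(targets)
  if (is.null(ids)) ids <- sprintf("%02d%06d", 1, seq_len(nz))
  rows_per_zone <- cells_per_zone / ncol
  nr <- rows_per_zone * nz
  zones <- matrix(rep(ids, each = rows_per_zone), nr, ncol)
  ag <- matrix(0L, nr, ncol)
  tile <- matrix(0L, nr, ncol)
  for (i in seq_len(nz)) {
    zone_cells <- which(zones == ids[i])
    n_ag <- round(ag_fraction * length(zone_cells))
    ag_cells <- sample(zone_cells, n_ag)
    ag[ag_cells] <- 1L
    n_tile <- round(targets[i] * n_ag)
    if (n_tile > 0) tile[sample(ag_cells, n_tile)] <- 1L
  }
  list(tile = tile, ag = ag, zones = zones, cell_area_m2 = cell_area_m2)
}

#' Simulate a fully consistent synthetic bundle
#'
#' Metrics plus a component flux table whose recomputed budgets reproduce
#' the metrics' surplus and efficiency (after sign reconciliation, see
#' [reconcile_efficiency()]).
#'
#' @param cfg A [simulation_config()].
#' @return A list with `metrics`, `fluxes` and `config`.
#' @export
simulate_bundle <- function(cfg = simulation_config()) {
  metrics <- reconcile_efficiency(simulate_metrics(cfg))
  fluxes <- simulate_fluxes(metrics, seed = cfg$seed + 1L)
  list(metrics = metrics, fluxes = fluxes, config = cfg)
}
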