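#' Table readers/writers and the pipeline driver
#'
#' All tables are UTF-8 comma-separated files with a header row, "." as the
#' decimal mark and empty fields for missing values. Watershed ids are
#' text, zero-padded to 8 characters (HUC8 codes); the basin id is the
#' first two characters (HUC2 nesting). Readers preserve leading zeros.
#'
#' @name io
NULL

.metrics_required <- c(
  "watershed_id", "area_km2", "pct_land", "pct_cropland", "pct_pasture",
  "pct_ag", "n_surplus", "p_surplus", "nue", "pue", "pct_tile_of_ag",
  "pct_nonbuffered_ws", "pct_prw_of_ag"
)

.metrics_pct_cols <- c("pct_land", "pct_cropland", "pct_pasture", "pct_ag",
                       "pct_tile_of_ag", "pct_nonbuffered_ws", "pct_prw_of_ag")

#' Read a subwatershed metrics table
#'
#' Validates the schema: all required columns present, ids unique, percent
#' columns in [0, 100] and area positive. Rows violating a row-level
#' invariant are rejected with a row-numbered warning; the remaining rows
#' load normally. A missing column is an error.
#'
#' @param path Path to a metrics CSV.
#' @return A tibble of validated metrics (with `basin_id` derived).
#' @export
read_metrics <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    watershed_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(.metrics_required, names(df))
  if (length(missing_cols)) {
    stop("metrics file missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$watershed_id)) {
    stop("duplicate watershed_id in ", path, call. = FALSE)
  }
  bad <- rep(FALSE, nrow(df))
  for (cl in .metrics_pct_cols) {
    v <- df[[cl]]
    bad <- bad | (!is.na(v) & (v < 0 | v > 100))
  }
  bad <- bad | (!is.na(df$area_km2) & df$area_km2 <= 0)
  if (any(bad)) {
    warning("rejected row(s) failing invariants (row ",
            paste(which(bad), collapse = ", "), ") in ", path, call. = FALSE)
    df <- df[!bad, ]
  }
  df$basin_id <- substr(df$watershed_id, 1, 2)
  df
}

#' @rdname read_metrics
#' @param metrics A metrics tibble.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_csv(metrics, path, na = "")
  invisible(path)
}

#' Read / write component flux tables
#'
#' @param path Path to a fluxes CSV in the [validate_fluxes()] schema.
#' @return A validated flux tibble.
#' @export
read_fluxes <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    watershed_id = readr::col_character(),
    nutrient = readr::col_character(),
    year = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_fluxes(df)
  df
}

#' @rdname read_fluxes
#' @param fluxes A flux tibble.
#' @export
write_fluxes <- function(fluxes, path) {
  readr::write_csv(fluxes, path, na = "")
  invisible(path)
}

#' Read a pipeline/threshold configuration from YAML
#'
#' Recognized keys: the six thresholds of [threshold_set()] plus
#' `min_pct_land` (coverage filter, default 1.5). Unknown keys error.
#'
#' @param path Path to a YAML file.
#' @return A list with `thresholds` (a `threshold_set`) and `min_pct_land`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  thr_keys <- names(formals(threshold_set))
  unknown <- setdiff(names(raw), c(thr_keys, "min_pct_land"))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  thr <- do.call(threshold_set, raw[intersect(names(raw), thr_keys)])
  list(thresholds = thr,
       min_pct_land = if (!is.null(raw$min_pct_land)) raw$min_pct_land else 1.5)
}

#' Run the full prioritization pipeline
#'
#' Stages: budget (only when a flux table is supplied) -> coverage filter
#' (`pct_land >= min_pct_land`, mirroring the exclusion of coastal
#' subwatersheds) -> per-nutrient classification -> summaries. Record
#' counts surviving each stage are reported via `message()`. All outputs
#' are written as CSV under `out_dir`.
#'
#' @param metrics Metrics tibble or path to a metrics CSV.
#' @param fluxes Optional flux tibble or path; when supplied, multi-year
#'   mean surplus/efficiency computed from it replace the metrics table's
#'   surplus and efficiency columns.
#' @param thresholds A [threshold_set()].
#' @param min_pct_land Coverage filter on percent land area (default 1.5).
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param spearman_metrics Columns for the correlation matrix (area-based
#'   metrics when present).
#' @param summary_metrics Percent columns for the basin median/IQR table.
#' @return Invisibly, a list with `metrics` (filtered), `assignments`,
#'   `tally`, `aggregates`, `correlations`, `basin_summary`.
#' @export
run_pipeline <- function(metrics, fluxes = NULL,
                         thresholds = threshold_set(), min_pct_land = 1.5,
                         out_dir = NULL,
                         spearman_metrics = NULL, summary_metrics = NULL) {
  if (is.character(metrics)) metrics <- read_metrics(metrics)
  message("metrics records: ", nrow(metrics))

  if (!is.null(fluxes)) {
    if (is.character(fluxes)) fluxes <- read_fluxes(fluxes)
    budget <- multiyear_mean(compute_budget(fluxes))
    wide <- tidyr::pivot_wider(
      budget[, c("watershed_id", "nutrient", "surplus_kg_ha_yr", "efficiency")],
      names_from = "nutrient",
      values_from = c("surplus_kg_ha_yr", "efficiency")
    )
    names(wide) <- c("watershed_id", "n_surplus", "p_surplus", "nue", "pue")
    keep <- setdiff(names(metrics), c("n_surplus", "p_surplus", "nue", "pue"))
    metrics <- dplyr::inner_join(metrics[, keep], wide, by = "watershed_id")
    message("budget stage: ", nrow(budget), " watershed-nutrient budgets")
  } else {
    message("budget stage skipped (no flux table supplied)")
  }

  metrics <- metrics[is.na(metrics$pct_land) | metrics$pct_land >= min_pct_land, ]
  message("after coverage filter (pct_land >= ", min_pct_land, "): ",
          nrow(metrics))

  assignments <- classify_table(metrics, thresholds)
  for (nu in unique(assignments$nutrient)) {
    a <- assignments[assignments$nutrient == nu, ]
    message(nu, ": ", sum(a$priority, na.rm = TRUE), " priority, ",
            sum(a$input_reduction), " in-field branch")
  }

  tl <- tally(assignments)
  agg <- tally_aggregates(assignments)
  if (is.null(spearman_metrics)) {
    area_cols <- c("ag_area_km2", "pasture_area_km2", "tile_area_km2",
                   "nonbuffered_area_km2", "prw_area_km2",
                   "n_surplus", "p_surplus")
    spearman_metrics <- intersect(area_cols, names(metrics))
  }
  corr <- if (length(spearman_metrics) >= 2 && nrow(metrics) >= 3) {
    spearman_matrix(metrics, spearman_metrics)
  } else NULL
  if (is.null(summary_metrics)) {
    summary_metrics <- intersect(
      c(.metrics_pct_cols, "nue", "pue", "n_surplus", "p_surplus"),
      names(metrics)
    )
  }
  bs <- basin_summary(metrics, summary_metrics)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(assignments, file.path(out_dir, "strategies.csv"), na = "")
    readr::write_csv(tl, file.path(out_dir, "tally.csv"), na = "")
    readr::write_csv(agg, file.path(out_dir, "tally_aggregates.csv"), na = "")
    readr::write_csv(bs, file.path(out_dir, "basin_summary.csv"), na = "")
    if (!is.null(corr)) {
      cm <- tibble::as_tibble(corr$rho, rownames = "metric")
      readr::write_csv(cm, file.path(out_dir, "correlations.csv"), na = "")
    }
    write_metrics(metrics, file.path(out_dir, "metrics_filtered.csv"))
  }
  invisible(list(metrics = metrics, assignments = assignments, tally = tl,
                 aggregates = agg, correlations = corr, basin_summary = bs))
}
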