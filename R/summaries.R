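#' Reporting products: tallies, shares, correlations, basin summaries
#'
#' @name summaries
NULL

.basin_of <- function(watershed_id) substr(watershed_id, 1, 2)

#' Tally strategy assignments by basin and nationally
#'
#' Counts subwatersheds in each strategy class per nutrient, grouped by
#' HUC2 river basin (first two characters of the watershed id) and/or
#' nationally ("CONUS"). The grid of (group, nutrient, class) is complete,
#' with explicit zeros, so counts always sum to the group's record count.
#'
#' @param assignments Tibble from [classify_table()].
#' @param group_by `"basin"`, `"CONUS"`, or both.
#' @return A tibble: `basin_id` (`"CONUS"` for the national rows),
#'   `nutrient`, `strategy_class`, `n`.
#' @export
tally <- function(assignments, group_by = c("basin", "CONUS")) {
  group_by <- match.arg(group_by, several.ok = TRUE)
  pieces <- list()
  if ("basin" %in% group_by) {
    b <- assignments
    b$basin_id <- .basin_of(b$watershed_id)
    pieces$basin <- dplyr::count(b, .data$basin_id, .data$nutrient,
                                 .data$strategy_class)
  }
  if ("CONUS" %in% group_by) {
    cc <- dplyr::count(assignments, .data$nutrient, .data$strategy_class)
    cc$basin_id <- "CONUS"
    pieces$conus <- cc[, c("basin_id", "nutrient", "strategy_class", "n")]
  }
  out <- dplyr::bind_rows(pieces)
  grid <- tidyr::expand_grid(
    basin_id = unique(out$basin_id),
    nutrient = unique(out$nutrient),
    strategy_class = strategy_classes
  )
  out <- dplyr::left_join(grid, out,
                          by = c("basin_id", "nutrient", "strategy_class"))
  out$n[is.na(out$n)] <- 0L
  out
}

#' Derived prioritization-step counts
#'
#' Aggregates mirroring how the national study reports its results: the
#' number of priority (high-surplus) subwatersheds, the in-field branch
#' (efficiency below threshold), the stacked subset of that branch (in-field
#' plus any edge-of-field measure), and the edge-of-field branch.
#'
#' @inheritParams tally
#' @return A tibble: `basin_id`, `nutrient`, `measure`, `n`, where
#'   `measure` is one of `total`, `priority`, `in_field_branch`,
#'   `stacked`, `edge_branch`, `unclassified`.
#' @export
tally_aggregates <- function(assignments, group_by = c("basin", "CONUS")) {
  group_by <- match.arg(group_by, several.ok = TRUE)
  agg_one <- function(df, basin_label) {
    dplyr::bind_rows(lapply(split(df, df$nutrient), function(g) {
      classified <- is.na(g$missing_reason)
      infield <- g$input_reduction
      stacked <- infield & g$strategy_class != "INFIELD_ONLY"
      tibble::tibble(
        basin_id = basin_label,
        nutrient = g$nutrient[1],
        measure = c("total", "priority", "in_field_branch", "stacked",
                    "edge_branch", "unclassified"),
        n = c(nrow(g),
              sum(g$priority & classified, na.rm = TRUE),
              sum(infield),
              sum(stacked),
              sum(!infield & g$priority & classified, na.rm = TRUE),
              sum(!classified))
      )
    }))
  }
  pieces <- list()
  if ("basin" %in% group_by) {
    b <- split(assignments, .basin_of(assignments$watershed_id))
    pieces$basin <- dplyr::bind_rows(
      lapply(names(b), function(id) agg_one(b[[id]], id))
    )
  }
  if ("CONUS" %in% group_by) {
    pieces$conus <- agg_one(assignments, "CONUS")
  }
  dplyr::bind_rows(pieces)
}

#' Percentage share, rounded to one decimal
#'
#' Matches the reporting convention for shares like "928 (85.8%) of the
#' 1082": 100 * count / total, rounded half away from zero to one decimal.
#'
#' @param count Numerator count(s), `0 <= count <= total`.
#' @param total Denominator total(s), > 0.
#' @return Percentage(s) rounded to 1 decimal.
#' @export
percent_share <- function(count, total) {
  if (any(total <= 0)) stop("total must be > 0", call. = FALSE)
  if (any(count < 0 | count > total)) {
    stop("count must be between 0 and total", call. = FALSE)
  }
  x <- 100 * count / total
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Share of the net national surplus held by priority subwatersheds
#'
#' Numerator: total surplus mass (per-ha surplus times area) over priority
#' subwatersheds; denominator: the same sum over all subwatersheds.
#' Negative surpluses (soil mining) stay in both sums — the denominator is
#' the *net* surplus — so the share can exceed 100%.
#'
#' @param metrics Metrics table with `watershed_id`, `area_km2`,
#'   `n_surplus`, `p_surplus`.
#' @param assignments Assignments from [classify_table()].
#' @param nutrient `"N"` or `"P"`.
#' @return Percentage (not rounded).
#' @export
net_surplus_share <- function(metrics, assignments, nutrient) {
  nutrient <- match.arg(nutrient, c("N", "P"))
  asg <- assignments[assignments$nutrient == nutrient, ]
  j <- dplyr::inner_join(
    metrics, asg[, c("watershed_id", "priority")], by = "watershed_id"
  )
  surplus <- if (nutrient == "N") j$n_surplus else j$p_surplus
  mass <- surplus * j$area_km2
  denom <- sum(mass)
  if (denom <= 0) {
    stop("net national surplus is not positive (", signif(denom, 4),
         "); share undefined", call. = FALSE)
  }
  100 * sum(mass[!is.na(j$priority) & j$priority]) / denom
}

#' Spearman rank-correlation matrix with pairwise-complete deletion
#'
#' Average ranks are used for ties. A metric constant across records has
#' no rank variance; its correlations are `NA` with a warning.
#'
#' @param records Data frame of metrics.
#' @param metric_list Character vector of column names (>= 2).
#' @return A list of class `"spearman_matrix"` with `rho` (symmetric
#'   matrix, unit diagonal) and `n_pairs` (complete pairs per cell).
#' @export
spearman_matrix <- function(records, metric_list) {
  stopifnot(length(metric_list) >= 2, all(metric_list %in% names(records)))
  x <- as.matrix(records[, metric_list])
  if (nrow(x) < 3) stop("need at least 3 records", call. = FALSE)
  constant <- apply(x, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && length(unique(v)) == 1
  })
  if (any(constant)) {
    warning("constant metric(s): ", paste(metric_list[constant], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  }
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  )
  diag(rho) <- 1
  ok <- !is.na(x)
  n_pairs <- crossprod(ok * 1L)
  structure(list(rho = rho, n_pairs = n_pairs), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat("Spearman rank correlations (pairwise complete):\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Median and interquartile range of percent metrics by river basin
#'
#' Quantiles use linear interpolation between order statistics (R's
#' default, type 7).
#'
#' @param records Metrics table with `watershed_id` (basin = first two
#'   characters).
#' @param metric_list Columns to summarize.
#' @return A tibble: `basin_id`, `metric`, `n`, `q25`, `median`, `q75`.
#' @export
basin_summary <- function(records, metric_list) {
  stopifnot(all(metric_list %in% names(records)))
  long <- tidyr::pivot_longer(
    records[, c("watershed_id", metric_list)],
    dplyr::all_of(metric_list), names_to = "metric", values_to = "value"
  )
  long$basin_id <- .basin_of(long$watershed_id)
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$basin_id, .data$metric),
    n = sum(!is.na(.data$value)),
    q25 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
    median = stats::quantile(.data$value, 0.5, na.rm = TRUE, names = FALSE),
    q75 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
    .groups = "drop"
  )
  empty <- out$n == 0
  if (any(empty)) {
    warning("basin(s) with no data for some metric omitted: ",
            paste(unique(out$basin_id[empty]), collapse = ", "), call. = FALSE)
    out <- out[!empty, ]
  }
  out
}
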