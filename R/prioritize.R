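#' Threshold decision tree for conservation-strategy classification
#'
#' Each subwatershed passes through five gates, separately for N and P:
#'
#' 1. **Priority** — is the nutrient surplus high (>= 7 kg-N ha^-1 yr^-1 or
#'    >= 1 kg-P ha^-1 yr^-1)? Non-priority subwatersheds exit immediately.
#' 2. **Input reduction** — is nutrient use efficiency below 0.7? If so,
#'    in-field input reduction (nutrient management) leads the strategy;
#'    at or above 0.7 the farmers already operate efficiently and the
#'    strategy leads with edge-of-field measures. Preventing nutrients from
#'    leaving fields (cover crops, reduced tillage) applies to every
#'    priority subwatershed regardless of efficiency.
#' 3. **Drainage management** — is >= 30% of agricultural land tile-drained?
#' 4. **Buffers** — is nonbuffered agriculture >= 2% of the watershed?
#' 5. **Wetlands** — where edge-of-field treatment is needed (buffer or
#'    drainage flag set), are potentially restorable wetlands >= 10% of
#'    agricultural land?
#'
#' Boundary semantics follow the published wording exactly: `>=` for the
#' surplus, tile, nonbuffered and wetland gates; strict `<` for the
#' efficiency gate (a subwatershed at exactly 0.7 goes to the edge-of-field
#' branch).
#'
#' @name prioritization
NULL

#' Strategy class labels
#' @export
strategy_classes <- c(
  "NOT_PRIORITY", "INFIELD_ONLY", "INFIELD_WETLAND",
  "INFIELD_WETLAND_DRAINAGE", "INFIELD_BUFFER", "INFIELD_BUFFER_DRAINAGE",
  "EDGE_WETLAND", "EDGE_WETLAND_DRAINAGE", "EDGE_BUFFER",
  "EDGE_BUFFER_DRAINAGE", "UNCLASSIFIED_MISSING"
)

#' Construct a validated threshold set
#'
#' Defaults are the national-analysis values: surpluses at the CONUS
#' medians (7 kg-N, 1 kg-P ha^-1 yr^-1), efficiency at 0.7 (~75th
#' percentile and a broadly promoted stewardship goal), tile at 30% of
#' agricultural land (~95th percentile), nonbuffered agriculture at 2% of
#' the watershed (40th percentile), and restorable wetlands at 10% of
#' agricultural land (~median).
#'
#' @param surplus_n High-N-surplus cutoff, kg-N ha^-1 yr^-1.
#' @param surplus_p High-P-surplus cutoff, kg-P ha^-1 yr^-1.
#' @param efficiency Efficiency cutoff (dimensionless, in (0, 2]).
#' @param tile_pct Percent tile drainage of agricultural land.
#' @param nonbuffered_pct Percent nonbuffered agriculture of watershed.
#' @param prw_pct Percent potentially restorable wetlands of agricultural
#'   land.
#' @return A list of class `"threshold_set"`.
#' @export
threshold_set <- function(surplus_n = 7, surplus_p = 1, efficiency = 0.7,
                          tile_pct = 30, nonbuffered_pct = 2, prw_pct = 10) {
  t <- list(surplus_n = surplus_n, surplus_p = surplus_p,
            efficiency = efficiency, tile_pct = tile_pct,
            nonbuffered_pct = nonbuffered_pct, prw_pct = prw_pct)
  vals <- unlist(t)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be finite and > 0", call. = FALSE)
  }
  if (efficiency > 2) stop("efficiency threshold must be in (0, 2]", call. = FALSE)
  structure(t, class = "threshold_set")
}

#' Evaluate the decision-tree flags for one nutrient
#'
#' Vectorized over the rows of a metrics table. Missing metrics are allowed
#' only when the record short-circuits at the surplus gate; a priority
#' record with a missing downstream metric is flagged
#' `UNCLASSIFIED_MISSING` with the reason recorded.
#'
#' @param metrics Tibble of subwatershed metrics (columns `watershed_id`,
#'   `n_surplus`, `p_surplus`, `nue`, `pue`, `pct_tile_of_ag`,
#'   `pct_nonbuffered_ws`, `pct_prw_of_ag`).
#' @param thresholds A [threshold_set()].
#' @param nutrient `"N"` or `"P"`.
#' @return A tibble with one row per record: logical flags `priority`,
#'   `input_reduction`, `field_loss_prevention`, `drainage_mgmt`,
#'   `buffer_needed`, `wetland_suitable`, plus `missing_reason`.
#' @export
evaluate_flags <- function(metrics, thresholds = threshold_set(), nutrient) {
  nutrient <- match.arg(nutrient, c("N", "P"))
  surplus <- if (nutrient == "N") metrics$n_surplus else metrics$p_surplus
  eff <- if (nutrient == "N") metrics$nue else metrics$pue
  s_thr <- if (nutrient == "N") thresholds$surplus_n else thresholds$surplus_p

  n <- nrow(metrics)
  priority <- surplus >= s_thr                   # NA when surplus missing
  input_reduction <- rep(FALSE, n)
  drainage <- rep(FALSE, n)
  buffer <- rep(FALSE, n)
  wetland <- rep(FALSE, n)
  reason <- rep(NA_character_, n)

  reason[is.na(priority)] <- paste0(tolower(nutrient), " surplus missing")

  act <- !is.na(priority) & priority
  if (any(act)) {
    need <- list(
      efficiency = eff,
      pct_tile_of_ag = metrics$pct_tile_of_ag,
      pct_nonbuffered_ws = metrics$pct_nonbuffered_ws
    )
    for (nm in names(need)) {
      bad <- act & is.na(need[[nm]]) & is.na(reason)
      reason[bad] <- paste(nm, "missing")
    }
    ok <- act & is.na(reason)
    input_reduction[ok] <- eff[ok] < thresholds$efficiency
    drainage[ok] <- metrics$pct_tile_of_ag[ok] >= thresholds$tile_pct
    buffer[ok] <- metrics$pct_nonbuffered_ws[ok] >= thresholds$nonbuffered_pct
    # wetland suitability matters only where edge-of-field treatment arises
    eval_wet <- ok & (drainage | buffer)
    wet_missing <- eval_wet & is.na(metrics$pct_prw_of_ag)
    reason[wet_missing] <- "pct_prw_of_ag missing"
    eval_wet <- eval_wet & !wet_missing
    wetland[eval_wet] <- metrics$pct_prw_of_ag[eval_wet] >= thresholds$prw_pct
    # a record that became unclassifiable carries no partial flags
    undo <- act & !is.na(reason)
    input_reduction[undo] <- FALSE
    drainage[undo] <- FALSE
    buffer[undo] <- FALSE
    wetland[undo] <- FALSE
  }

  field_loss <- !is.na(priority) & priority & is.na(reason)
  tibble::tibble(
    watershed_id = metrics$watershed_id,
    nutrient = nutrient,
    priority = priority,
    input_reduction = input_reduction,
    field_loss_prevention = field_loss,
    drainage_mgmt = drainage,
    buffer_needed = buffer,
    wetland_suitable = wetland,
    missing_reason = reason
  )
}

#' Map decision-tree flags to a strategy class label
#'
#' In-field branch (efficiency below threshold, `input_reduction` true):
#' no drainage and no buffer need gives `INFIELD_ONLY`; otherwise wetlands
#' (where suitable) or non-wetland buffers are stacked with in-field
#' conservation, with a `_DRAINAGE` suffix where tile effluent must also be
#' managed. The edge-of-field branch maps identically with an `EDGE_`
#' prefix, except that a record needing neither drainage management nor
#' buffers falls back to `INFIELD_ONLY` (field-loss prevention is all that
#' remains — e.g. a high-efficiency, well-buffered subwatershed).
#'
#' @param flags A tibble as returned by [evaluate_flags()].
#' @return Character vector of class labels, one per row.
#' @export
assign_class <- function(flags) {
  n <- nrow(flags)
  cls <- rep(NA_character_, n)
  cls[!is.na(flags$missing_reason)] <- "UNCLASSIFIED_MISSING"
  not_pri <- is.na(cls) & !flags$priority
  cls[not_pri] <- "NOT_PRIORITY"
  todo <- is.na(cls)
  if (any(todo)) {
    d <- flags$drainage_mgmt
    b <- flags$buffer_needed
    w <- flags$wetland_suitable
    edge_needed <- d | b
    base <- ifelse(!edge_needed, "INFIELD_ONLY",
            ifelse(w, "WETLAND", "BUFFER"))
    stacked <- ifelse(base == "INFIELD_ONLY", base,
                      paste0(base, ifelse(d, "_DRAINAGE", "")))
    prefix <- ifelse(flags$input_reduction, "INFIELD_", "EDGE_")
    lab <- ifelse(stacked == "INFIELD_ONLY", "INFIELD_ONLY",
                  paste0(prefix, stacked))
    cls[todo] <- lab[todo]
  }
  stopifnot(all(cls %in% strategy_classes))
  cls
}

#' Classify a metrics table for both nutrients
#'
#' Runs the decision tree independently for N and P over every record,
#' yielding `2 * nrow(metrics)` strategy assignments (the two nutrients can
#' differ in sources and transport, so their prioritizations are kept
#' separate).
#'
#' @inheritParams evaluate_flags
#' @param nutrients Which nutrients to classify.
#' @return A tibble of flags plus `strategy_class`.
#' @export
classify_table <- function(metrics, thresholds = threshold_set(),
                           nutrients = c("N", "P")) {
  if (anyDuplicated(metrics$watershed_id)) {
    stop("duplicate watershed_id in metrics table", call. = FALSE)
  }
  out <- lapply(nutrients, function(nu) {
    fl <- evaluate_flags(metrics, thresholds, nu)
    fl$strategy_class <- assign_class(fl)
    fl
  })
  dplyr::bind_rows(out)
}

#' Scan classifications over a grid of thresholds
#'
#' Explores sensitivity of the prioritization to threshold choice. Each
#' supplied axis replaces the corresponding default; all combinations are
#' evaluated and tallied.
#'
#' @param metrics Metrics table as for [classify_table()].
#' @param threshold_grid Named list of numeric vectors over any of
#'   `surplus_n`, `surplus_p`, `efficiency`, `tile_pct`,
#'   `nonbuffered_pct`, `prw_pct`. Unlisted thresholds stay at their
#'   defaults.
#' @param nutrients Which nutrients to classify.
#' @return A tibble with one row per (threshold combination, nutrient):
#'   the threshold values, flag counts (`n_priority`, `n_input_reduction`,
#'   `n_drainage_mgmt`, `n_buffer_needed`, `n_wetland_suitable`) and one
#'   count column per strategy class (`n_<CLASS>`).
#' @export
sensitivity_scan <- function(metrics, threshold_grid,
                             nutrients = c("N", "P")) {
  if (!length(threshold_grid)) stop("empty threshold grid", call. = FALSE)
  allowed <- names(formals(threshold_set))
  bad <- setdiff(names(threshold_grid), allowed)
  if (length(bad)) stop("unknown threshold axis: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(vapply(threshold_grid, function(v) length(v) == 0 || is.unsorted(v),
                 logical(1)))) {
    stop("each grid axis must be non-empty and sorted", call. = FALSE)
  }
  combos <- expand.grid(threshold_grid, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    thr <- do.call(threshold_set, as.list(combos[i, , drop = FALSE]))
    asg <- classify_table(metrics, thr, nutrients)
    per_nut <- dplyr::group_by(asg, .data$nutrient)
    counts <- dplyr::summarise(
      per_nut,
      n_priority = sum(.data$priority, na.rm = TRUE),
      n_input_reduction = sum(.data$input_reduction),
      n_drainage_mgmt = sum(.data$drainage_mgmt),
      n_buffer_needed = sum(.data$buffer_needed),
      n_wetland_suitable = sum(.data$wetland_suitable),
      .groups = "drop"
    )
    cls <- dplyr::count(asg, .data$nutrient, .data$strategy_class)
    cls <- tidyr::pivot_wider(
      cls, names_from = "strategy_class", values_from = "n",
      names_prefix = "n_", values_fill = 0L
    )
    out <- dplyr::left_join(counts, cls, by = "nutrient")
    dplyr::bind_cols(combos[rep(i, nrow(out)), , drop = FALSE], out)
  })
  out <- dplyr::bind_rows(rows)
  # classes absent from every combo still get a zero column for stability
  for (cl in strategy_classes) {
    col <- paste0("n_", cl)
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  tibble::as_tibble(out)
}
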