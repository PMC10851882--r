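#' Agricultural nutrient budgets from component fluxes
#'
#' The agricultural surplus of a nutrient is the difference between
#' farm-associated inputs and outputs, normalized per total watershed
#' hectare. For nitrogen the inputs are synthetic fertilizer, cultivated
#' biological fixation, atmospheric deposition onto farmland and livestock
#' waste; for phosphorus only fertilizer and livestock waste (fixation and
#' deposition do not apply). The single output is crop removal. Nutrient use
#' efficiency is the ratio of outputs to inputs.
#'
#' Negative surpluses are retained: they indicate soil mining, where crop
#' removal draws down soil nutrient reserves faster than new inputs arrive.
#'
#' @name budget
NULL

.flux_cols <- c(
  "watershed_id", "nutrient", "year", "fertilizer_kg", "fixation_kg",
  "deposition_kg", "livestock_kg", "crop_removal_kg", "watershed_area_ha"
)

#' Validate a table of component flux records
#'
#' Checks the invariants of the flux schema: all component fluxes
#' non-negative, positive watershed area, and zero fixation/deposition for
#' phosphorus records (those pathways are nitrogen-only).
#'
#' @param fluxes A data frame with columns `watershed_id`, `nutrient`
#'   (`"N"`/`"P"`), `year`, `fertilizer_kg`, `fixation_kg`, `deposition_kg`,
#'   `livestock_kg`, `crop_removal_kg` (all kg yr^-1) and
#'   `watershed_area_ha` (ha).
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_fluxes <- function(fluxes) {
  missing_cols <- setdiff(.flux_cols, names(fluxes))
  if (length(missing_cols)) {
    stop("flux table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(fluxes$nutrient %in% c("N", "P"))) {
    stop("nutrient must be 'N' or 'P'", call. = FALSE)
  }
  comp <- c("fertilizer_kg", "fixation_kg", "deposition_kg", "livestock_kg",
            "crop_removal_kg")
  bad_neg <- vapply(comp, function(cl) any(fluxes[[cl]] < 0, na.rm = TRUE), logical(1))
  if (any(bad_neg)) {
    stop("negative component flux in: ", paste(comp[bad_neg], collapse = ", "),
         call. = FALSE)
  }
  if (any(fluxes$watershed_area_ha <= 0, na.rm = TRUE)) {
    stop("watershed_area_ha must be > 0 for every record", call. = FALSE)
  }
  is_p <- fluxes$nutrient == "P"
  if (any(is_p & (fluxes$fixation_kg != 0 | fluxes$deposition_kg != 0))) {
    stop("phosphorus records must have zero fixation_kg and deposition_kg",
         call. = FALSE)
  }
  invisible(fluxes)
}

#' Total nutrient-appropriate inputs and outputs
#' @noRd
.budget_totals <- function(fluxes) {
  n_extra <- ifelse(fluxes$nutrient == "N",
                    fluxes$fixation_kg + fluxes$deposition_kg, 0)
  tibble::tibble(
    total_inputs = fluxes$fertilizer_kg + fluxes$livestock_kg + n_extra,
    total_outputs = fluxes$crop_removal_kg
  )
}

#' Compute per-area nutrient surplus
#'
#' Surplus = (inputs - crop removal) / watershed area, in kg ha^-1 yr^-1,
#' per flux record. Negative values (soil mining) are kept as-is.
#'
#' @inheritParams validate_fluxes
#' @return A tibble with `watershed_id`, `nutrient`, `year`,
#'   `surplus_kg_ha_yr`, `total_inputs_kg`, `total_outputs_kg`.
#' @examples
#' flux <- tibble::tibble(
#'   watershed_id = "07080105", nutrient = "N", year = 2012,
#'   fertilizer_kg = 50, fixation_kg = 20, deposition_kg = 5,
#'   livestock_kg = 10, crop_removal_kg = 60, watershed_area_ha = 1
#' )
#' compute_surplus(flux)$surplus_kg_ha_yr  # 25
#' @export
compute_surplus <- function(fluxes) {
  validate_fluxes(fluxes)
  tot <- .budget_totals(fluxes)
  tibble::tibble(
    watershed_id = fluxes$watershed_id,
    nutrient = fluxes$nutrient,
    year = fluxes$year,
    surplus_kg_ha_yr = (tot$total_inputs - tot$total_outputs) / fluxes$watershed_area_ha,
    total_inputs_kg = tot$total_inputs,
    total_outputs_kg = tot$total_outputs
  )
}

#' Compute nutrient use efficiency
#'
#' Efficiency is outputs / inputs. It can exceed 1 when crop removal draws
#' on soil reserves. Records with zero total inputs get a missing
#' efficiency (`NA`) with a warning — the ratio is undefined and such
#' records are excluded from efficiency-gated classification downstream.
#'
#' @inheritParams validate_fluxes
#' @return A tibble with `watershed_id`, `nutrient`, `year`, `efficiency`,
#'   `total_inputs_kg`, `total_outputs_kg`.
#' @export
compute_efficiency <- function(fluxes) {
  validate_fluxes(fluxes)
  tot <- .budget_totals(fluxes)
  eff <- ifelse(tot$total_inputs > 0, tot$total_outputs / tot$total_inputs, NA_real_)
  if (anyNA(eff)) {
    warning(sum(is.na(eff)), " record(s) with zero total inputs: efficiency set to NA",
            call. = FALSE)
  }
  tibble::tibble(
    watershed_id = fluxes$watershed_id,
    nutrient = fluxes$nutrient,
    year = fluxes$year,
    efficiency = eff,
    total_inputs_kg = tot$total_inputs,
    total_outputs_kg = tot$total_outputs
  )
}

#' Full per-record budget (surplus + efficiency)
#'
#' @inheritParams validate_fluxes
#' @return A tibble with one row per flux record: surplus, efficiency,
#'   totals.
#' @export
compute_budget <- function(fluxes) {
  sur <- compute_surplus(fluxes)
  eff <- suppressWarnings(compute_efficiency(fluxes))
  sur$efficiency <- eff$efficiency
  sur[, c("watershed_id", "nutrient", "year", "surplus_kg_ha_yr", "efficiency",
          "total_inputs_kg", "total_outputs_kg")]
}

#' Multi-year mean of budget results
#'
#' Averages surplus and efficiency over the supplied years for each
#' watershed/nutrient (the national inventory uses the mean of the census
#' years 2002, 2007 and 2012 to smooth short-term swings). Missing
#' efficiencies are excluded from the efficiency mean; the number of years
#' actually used for each quantity is reported.
#'
#' @param budget A tibble as returned by [compute_budget()] (may contain
#'   several watershed/nutrient combinations).
#' @return A tibble with one row per (watershed_id, nutrient):
#'   `surplus_kg_ha_yr`, `efficiency`, `n_years_used`, `n_years_efficiency`.
#' @export
multiyear_mean <- function(budget) {
  if (nrow(budget) == 0) stop("empty budget table", call. = FALSE)
  dup <- dplyr::count(budget, .data$watershed_id, .data$nutrient, .data$year)
  if (any(dup$n > 1)) {
    stop("duplicate (watershed_id, nutrient, year) rows in budget table",
         call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(budget, .data$watershed_id, .data$nutrient),
    surplus_kg_ha_yr = mean(.data$surplus_kg_ha_yr),
    n_years_used = dplyr::n(),
    n_years_efficiency = sum(!is.na(.data$efficiency)),
    efficiency = ifelse(all(is.na(.data$efficiency)), NA_real_,
                        mean(.data$efficiency, na.rm = TRUE)),
    .groups = "drop"
  )
}

#' Accumulate legacy nutrient surplus over a year range
#'
#' Legacy phosphorus is the cumulative P surplus stored in soils over a
#' historical window (1945-2001 in the national inventory). The cumulative
#' value is the inclusive sum of annual per-hectare surpluses; negative
#' years (soil mining) decrement the total.
#'
#' @param annual_surplus_per_ha Numeric vector of annual surpluses,
#'   kg ha^-1 yr^-1, one per year, in year order.
#' @param years Integer vector of the same length giving each value's year.
#' @param start_year,end_year Inclusive bounds of the accumulation window;
#'   default to the range of `years`.
#' @param watershed_id Optional id carried through to the output.
#' @return A one-row tibble: `watershed_id`, `start_year`, `end_year`,
#'   `cumulative_per_ha`, `n_years`.
#' @export
accumulate_legacy <- function(annual_surplus_per_ha, years,
                              start_year = min(years), end_year = max(years),
                              watershed_id = NA_character_) {
  if (length(annual_surplus_per_ha) != length(years)) {
    stop("annual_surplus_per_ha and years must have equal length", call. = FALSE)
  }
  wanted <- seq.int(start_year, end_year)
  keep <- years >= start_year & years <= end_year
  got <- years[keep]
  if (anyDuplicated(got)) stop("duplicate years in series", call. = FALSE)
  miss <- setdiff(wanted, got)
  if (length(miss)) {
    stop("missing year(s) in series: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(got)) stop("years must be in increasing order", call. = FALSE)
  tibble::tibble(
    watershed_id = watershed_id,
    start_year = start_year,
    end_year = end_year,
    cumulative_per_ha = sum(annual_surplus_per_ha[keep]),
    n_years = length(wanted)
  )
}
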