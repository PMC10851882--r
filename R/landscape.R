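#' Landscape metrics from land-cover grids
#'
#' The tile-drainage stage works on a fine binary prediction grid (1 =
#' tile-drained agricultural cell). The grid is coarsened by block
#' aggregation to fractional cover (e.g. 30 m -> 150 m with factor 5), then
#' summarized by watershed zone: tile area, agricultural area, and percent
#' tile of agricultural land. Grids are plain matrices, row-major with the
#' origin at the upper-left; no georeferencing math is needed for the
#' metrics themselves.
#'
#' @name landscape
NULL

#' Coarsen a binary grid to fractional cover
#'
#' Aggregates `factor` x `factor` blocks of a fine binary grid into one
#' coarse cell holding the fraction of fine cells equal to 1. The block
#' mean is used (not majority vote) because it conserves total mapped area
#' exactly: `sum(coarse) * factor^2 == sum(fine)`.
#'
#' Grids whose dimensions are not divisible by `factor` are padded on the
#' bottom/right with zeros (non-tile, non-agriculture); use the same policy
#' for the companion mask and zone grids so padded cells can be excluded.
#'
#' @param grid Numeric matrix of 0/1 (fractions are also accepted and
#'   averaged, so the operation composes).
#' @param factor Positive integer block size.
#' @return A numeric matrix of dimension `ceiling(dim(grid) / factor)` with
#'   values in [0, 1].
#' @export
coarsen_binary <- function(grid, factor) {
  if (!is.matrix(grid)) stop("grid must be a matrix", call. = FALSE)
  if (length(factor) != 1 || is.na(factor) || factor != as.integer(factor) ||
      factor <= 0) {
    stop("factor must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  grid <- pad_grid(grid, factor, fill = 0)
  nr <- nrow(grid); nc <- ncol(grid)
  row_groups <- rep(seq_len(nr / factor), each = factor)
  col_groups <- rep(seq_len(nc / factor), each = factor)
  a <- rowsum(grid, row_groups, reorder = TRUE)
  out <- t(rowsum(t(a), col_groups, reorder = TRUE))
  dimnames(out) <- NULL
  out / factor^2
}

#' Pad a grid on the bottom/right to a multiple of a block size
#'
#' @param grid A matrix.
#' @param factor Block size to pad to.
#' @param fill Fill value for padded cells (0 for tile/agriculture masks;
#'   use a reserved zone id for zone grids).
#' @return The padded matrix (unchanged if already divisible).
#' @export
pad_grid <- function(grid, factor, fill = 0) {
  nr <- nrow(grid); nc <- ncol(grid)
  pr <- (factor - nr %% factor) %% factor
  pc <- (factor - nc %% factor) %% factor
  if (pr > 0) grid <- rbind(grid, matrix(fill, pr, ncol(grid)))
  if (pc > 0) grid <- cbind(grid, matrix(fill, nrow(grid), pc))
  grid
}

#' Zonal tile-drainage percentages
#'
#' For each watershed zone, sums tile cover and agricultural cover (cell
#' counts for binary grids, fractional cover for coarsened grids), converts
#' to km^2, and computes percent tile drainage of agricultural land.
#' Zones with no agricultural area get a missing percentage with a warning.
#'
#' @param tile Numeric matrix of tile cover in [0, 1].
#' @param ag Numeric matrix of agricultural cover in [0, 1], same shape.
#' @param zones Matrix of zone identifiers (watershed codes), same shape.
#'   Cells with `NA` zone are excluded (e.g. padding).
#' @param cell_area_m2 Area of one cell in m^2.
#' @return A tibble: `watershed_id`, `tile_area_km2`, `ag_area_km2`,
#'   `pct_tile_of_ag`, ordered by id.
#' @export
zonal_percent <- function(tile, ag, zones, cell_area_m2) {
  if (!identical(dim(tile), dim(ag)) || !identical(dim(tile), dim(zones))) {
    stop("tile, ag and zones grids must share dimensions", call. = FALSE)
  }
  if (any(tile > ag + 1e-12, na.rm = TRUE)) {
    stop("tile cover exceeds agricultural cover in some cells", call. = FALSE)
  }
  keep <- !is.na(zones)
  z <- as.character(zones[keep])
  tile_sum <- tapply(tile[keep], z, sum)
  ag_sum <- tapply(ag[keep], z, sum)
  ids <- sort(names(ag_sum))
  km2 <- cell_area_m2 / 1e6
  ag_area <- as.numeric(ag_sum[ids]) * km2
  tile_area <- as.numeric(tile_sum[ids]) * km2
  pct <- ifelse(ag_area > 0, 100 * tile_area / ag_area, NA_real_)
  if (anyNA(pct)) {
    warning(sum(is.na(pct)), " zone(s) with no agricultural area: pct_tile_of_ag set to NA",
            call. = FALSE)
  }
  tibble::tibble(
    watershed_id = ids,
    tile_area_km2 = tile_area,
    ag_area_km2 = ag_area,
    pct_tile_of_ag = pct
  )
}

#' Percent of watershed area
#'
#' Expresses a component area as a percentage of total watershed area,
#' used e.g. for nonbuffered agriculture (which the classifier gates as a
#' percent of the whole watershed, not of agricultural land).
#'
#' @param component_area_km2 Component area(s), km^2.
#' @param watershed_area_km2 Total watershed area(s), km^2, > 0.
#' @return Numeric percentage(s) in [0, 100].
#' @export
percent_of_watershed <- function(component_area_km2, watershed_area_km2) {
  if (any(watershed_area_km2 <= 0)) {
    stop("watershed_area_km2 must be > 0", call. = FALSE)
  }
  if (any(component_area_km2 < 0)) {
    stop("component_area_km2 must be >= 0", call. = FALSE)
  }
  if (any(component_area_km2 > watershed_area_km2 * (1 + 1e-12))) {
    stop("component area exceeds watershed area", call. = FALSE)
  }
  100 * component_area_km2 / watershed_area_km2
}

#' Read / write single-band raster grids as TIFF
#'
#' Thin wrappers over the `tiff` package storing matrices as single-band
#' TIFF images. Values are stored as 32-bit floats; binary and fractional
#' grids round-trip within float precision.
#'
#' @param path File path.
#' @return `read_grid` returns a numeric matrix.
#' @export
read_grid <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' @rdname read_grid
#' @param grid Numeric matrix with values in [0, 1] (TIFF sample range).
#' @export
write_grid <- function(grid, path) {
  tiff::writeTIFF(grid, path, bits.per.sample = 32L)
  invisible(path)
}

#' Build a zone-id matrix from (row, col, zone) triples
#'
#' Zone grids for small fixtures are stored as plain CSV triples; this
#' expands them to a matrix. Unlisted cells are `NA` (excluded from zonal
#' statistics).
#'
#' @param triples Data frame with columns `row`, `col`, `zone`.
#' @param nrow,ncol Dimensions of the target grid.
#' @return A character matrix of zone ids.
#' @export
zones_from_triples <- function(triples, nrow, ncol) {
  stopifnot(all(c("row", "col", "zone") %in% names(triples)))
  if (any(triples$row < 1 | triples$row > nrow | triples$col < 1 |
          triples$col > ncol)) {
    stop("triple indices outside grid dimensions", call. = FALSE)
  }
  z <- matrix(NA_character_, nrow, ncol)
  z[cbind(triples$row, triples$col)] <- as.character(triples$zone)
  z
}
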