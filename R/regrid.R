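# Equal-area regridding, zone overlay and grain aggregation.
#
# All grids are axis-aligned rectangle tilings in the cylindrical equal-area
# working projection (x = R*lon_rad, y = R*sin(lat)), so spatial overlaps are
# exact products of 1-D interval overlaps and every operation below conserves
# area by construction.

#' Re-grid a land-use grid to an equal-area grid
#'
#' Builds a target grid of (near-)square equal-area cells spanning exactly the
#' source domain in the working projection: the side is
#' `sqrt(targetCellArea)` and the number of columns/rows is the nearest
#' integer count that tiles the domain, so realized cell areas can differ
#' slightly from the requested area but are identical across cells. Each
#' type's area in a target cell is the overlap-area-weighted sum of source
#' contributions, so global area per type per year is conserved exactly (up to
#' floating point).
#'
#' @param grid Source [LandUseGrid-class] (lon-lat or equal-area).
#' @param spec A [GridSpec] giving the target cell area in km^2.
#' @return An equal-area [LandUseGrid-class] with the same type labels and
#'   years.
#' @export
regridEqualArea <- function(grid, spec = GridSpec()) {
  stopifnot(is(grid, "LandUseGrid"), is(spec, "GridSpec"))
  validObject(spec)
  md <- metadata(grid)
  side <- sqrt(spec@targetCellArea)
  xr <- range(md$xEdges)
  yr <- range(md$yEdges)
  nx <- max(1L, as.integer(round(diff(xr) / side)))
  ny <- max(1L, as.integer(round(diff(yr) / side)))
  tx <- seq(xr[1L], xr[2L], length.out = nx + 1L)
  ty <- seq(yr[1L], yr[2L], length.out = ny + 1L)
  W <- .overlapOperator(tx, ty, md$xEdges, md$yEdges)
  targetArea <- (diff(xr) / nx) * (diff(yr) / ny)

  fbig <- do.call(cbind, as.list(assays(grid)))
  typeArea <- as.matrix(W %*% fbig)           # km^2 per target cell
  targetFrac <- typeArea / targetArea
  nTypes <- length(assays(grid))
  nYears <- ncol(grid)
  fractions <- lapply(seq_len(nTypes), function(j) {
    targetFrac[, ((j - 1L) * nYears + 1L):(j * nYears), drop = FALSE]
  })
  names(fractions) <- typeLabels(grid)
  landFrac <- landArea(grid) / cellArea(grid)
  targetLand <- as.numeric(W %*% landFrac)
  LandUseGrid(
    fractions = fractions, years = gridYears(grid),
    xEdges = tx, yEdges = ty,
    landArea = targetLand, gridType = "equalarea"
  )
}

#' Overlay biome and region zone maps onto a grid
#'
#' Computes the exact rectangle-overlap area between every grid cell and every
#' zone-map cell in the working projection. A grid cell overlapping two or
#' more biomes (by more than a 1e-9 relative area tolerance) is flagged
#' `isBoundary`; such cells are excluded from all downstream metric
#' computations (see [retainedCells()]). Every cell is assigned the biome and
#' region with the largest overlap. Counts of flagged and retained cells are
#' reported via `message()`.
#'
#' @param grid A [LandUseGrid-class].
#' @param zones A [ZoneMaps-class] covering the grid domain.
#' @return `grid` with `biomeId`, `regionId` and `isBoundary` columns added to
#'   its `rowData`.
#' @export
overlayZones <- function(grid, zones) {
  stopifnot(is(grid, "LandUseGrid"), is(zones, "ZoneMaps"))
  md <- metadata(grid)
  W <- .overlapOperator(md$xEdges, md$yEdges, zones@xEdges, zones@yEdges)
  covered <- Matrix::rowSums(W)
  if (any(covered < cellArea(grid) * (1 - 1e-6))) {
    .err("ecodivCoverageError",
         "%d grid cell(s) are not covered by the zone maps",
         sum(covered < cellArea(grid) * (1 - 1e-6)))
  }
  zoneOverlap <- function(labels) {
    ids <- sort(unique(labels))
    Z <- Matrix::sparseMatrix(
      i = seq_along(labels), j = match(labels, ids), x = 1,
      dims = c(length(labels), length(ids))
    )
    A <- as.matrix(W %*% Z)
    colnames(A) <- ids
    A
  }
  Ab <- zoneOverlap(zones@biome)
  Ar <- zoneOverlap(zones@region)
  tol <- 1e-9 * cellArea(grid)
  nBiomesHit <- rowSums(Ab > tol)
  isBoundary <- nBiomesHit >= 2L
  rd <- rowData(grid)
  rd$biomeId <- as.integer(colnames(Ab))[max.col(Ab, ties.method = "first")]
  rd$regionId <- as.integer(colnames(Ar))[max.col(Ar, ties.method = "first")]
  rd$isBoundary <- isBoundary
  rowData(grid) <- rd
  keep <- rd$landArea > 0 & !isBoundary
  message(sprintf(
    "overlayZones: %d cells flagged as biome-boundary, %d land cells retained",
    sum(isBoundary), sum(keep)
  ))
  grid
}

#' Aggregate a grid to a coarser grain
#'
#' Sums the type areas (and land areas) of `k` x `k` blocks of cells into one
#' coarse cell, so per-type area is conserved exactly on the aggregated
#' domain. Trailing partial blocks at the east/north edges are dropped with a
#' message. Zone columns, which pertain to the fine grid, are dropped;
#' re-run [overlayZones()] on the coarse grid if needed.
#'
#' @param grid A [LandUseGrid-class].
#' @param k Integer linear aggregation factor (>= 1); `k = 1` returns the
#'   input unchanged.
#' @return The aggregated [LandUseGrid-class].
#' @export
aggregateGrain <- function(grid, k) {
  stopifnot(is(grid, "LandUseGrid"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) {
    .err("ecodivParameterError", "grain factor k must be an integer >= 1")
  }
  if (k == 1L) return(grid)
  md <- metadata(grid)
  nxc <- md$nx %/% k
  nyc <- md$ny %/% k
  if (nxc < 1L || nyc < 1L) {
    .err("ecodivParameterError",
         "grain factor %d exceeds grid dimensions %d x %d", k, md$nx, md$ny)
  }
  dropX <- md$nx - nxc * k
  dropY <- md$ny - nyc * k
  if (dropX > 0L || dropY > 0L) {
    message(sprintf(
      "aggregateGrain: dropping %d trailing column(s) and %d row(s) not filling a %dx%d block",
      dropX, dropY, k, k
    ))
  }
  rd <- rowData(grid)
  keep <- rd$ix <= nxc * k & rd$iy <= nyc * k
  cx <- (rd$ix[keep] - 1L) %/% k + 1L
  cy <- (rd$iy[keep] - 1L) %/% k + 1L
  coarseId <- (cy - 1L) * nxc + cx
  nCoarse <- nxc * nyc
  Agg <- Matrix::sparseMatrix(i = coarseId, j = which(keep), x = 1,
                              dims = c(nCoarse, nrow(grid)))
  txc <- md$xEdges[seq(1L, nxc * k + 1L, by = k)]
  tyc <- md$yEdges[seq(1L, nyc * k + 1L, by = k)]
  wc <- diff(txc)
  hc <- diff(tyc)
  coarseArea <- wc[rep(seq_len(nxc), times = nyc)] *
    hc[rep(seq_len(nyc), each = nxc)]
  ca <- cellArea(grid)
  fractions <- lapply(as.list(assays(grid)), function(a) {
    as.matrix(Agg %*% (a * ca)) / coarseArea
  })
  coarseLand <- as.numeric(Agg %*% landArea(grid))
  lonE <- if (md$gridType == "lonlat") md$lonEdges[seq(1L, nxc * k + 1L, by = k)]
  latE <- if (md$gridType == "lonlat") md$latEdges[seq(1L, nyc * k + 1L, by = k)]
  LandUseGrid(
    fractions = fractions, years = gridYears(grid),
    xEdges = txc, yEdges = tyc,
    landArea = coarseLand, gridType = md$gridType,
    lonEdges = lonE, latEdges = latE
  )
}
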