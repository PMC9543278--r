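# Accessors and per-cell state for LandUseGrid.

#' @describeIn LandUseGrid-class Land-use / ecosystem type labels.
#' @param x,object A `LandUseGrid`.
#' @export
setGeneric("typeLabels", function(x) standardGeneric("typeLabels"))

#' @rdname LandUseGrid-class
#' @export
setMethod("typeLabels", "LandUseGrid", function(x) names(assays(x)))

#' @describeIn LandUseGrid-class Calendar years covered (column metadata).
#' @export
setGeneric("gridYears", function(x) standardGeneric("gridYears"))

#' @rdname LandUseGrid-class
#' @export
setMethod("gridYears", "LandUseGrid", function(x) colData(x)$year)

#' @describeIn LandUseGrid-class Per-cell total cell area (km^2).
#' @export
setGeneric("cellArea", function(x) standardGeneric("cellArea"))

#' @rdname LandUseGrid-class
#' @export
setMethod("cellArea", "LandUseGrid", function(x) rowData(x)$cellArea)

#' @describeIn LandUseGrid-class Per-cell land area (km^2).
#' @export
setGeneric("landArea", function(x) standardGeneric("landArea"))

#' @rdname LandUseGrid-class
#' @export
setMethod("landArea", "LandUseGrid", function(x) rowData(x)$landArea)

#' @describeIn LandUseGrid-class Logical vector of cells retained for metric
#'   computation: positive land area and, once zones are overlaid, not lying
#'   on a biome boundary.
#' @export
setGeneric("retainedCells", function(x) standardGeneric("retainedCells"))

#' @rdname LandUseGrid-class
#' @export
setMethod("retainedCells", "LandUseGrid", function(x) {
  keep <- landArea(x) > 0
  rd <- rowData(x)
  if ("isBoundary" %in% colnames(rd)) keep <- keep & !rd$isBoundary
  keep
})

#' @describeIn LandUseGrid-class Zone assignment table (after
#'   [overlayZones()]): `cell_id` (0-based, row-major from the south-west
#'   corner), `biome_id`, `region_id`, `is_boundary`.
#' @export
setGeneric("zoneAssignment", function(x) standardGeneric("zoneAssignment"))

#' @rdname LandUseGrid-class
#' @export
setMethod("zoneAssignment", "LandUseGrid", function(x) {
  rd <- rowData(x)
  if (!"biomeId" %in% colnames(rd)) {
    .err("ecodivParameterError", "no zones assigned; run overlayZones() first")
  }
  data.frame(
    cell_id = seq_len(nrow(x)) - 1L,
    biome_id = rd$biomeId,
    region_id = rd$regionId,
    is_boundary = rd$isBoundary
  )
})

setMethod("show", "LandUseGrid", function(object) {
  md <- metadata(object)
  cat(sprintf(
    "LandUseGrid: %d cells (%d x %d, %s), %d types, years %d-%d\n",
    nrow(object), md$nx, md$ny, md$gridType, length(assays(object)),
    min(gridYears(object)), max(gridYears(object))
  ))
  cat(sprintf(
    "  land cells: %d; retained: %d; mean cell area %.1f km^2\n",
    sum(landArea(object) > 0), sum(retainedCells(object)),
    mean(cellArea(object))
  ))
  cat("  types:", paste(utils::head(typeLabels(object), 9), collapse = ", "),
      if (length(assays(object)) > 9) "..." else "", "\n")
})

setMethod("show", "ScenarioParams", function(object) {
  cat(sprintf(
    "ScenarioParams: %d x %d cells, years %d-%d (onset %d), rate %.4g/yr, noise sd %.3g, %d biomes / %d regions, seed %d\n",
    object@nLon, object@nLat, object@yearStart, object@yearEnd,
    object@anthroOnsetYear, object@expansionRate, object@noiseSd,
    object@nBiomes, object@nRegions, object@seed
  ))
})

setMethod("show", "ClassificationScheme", function(object) {
  cat(sprintf("ClassificationScheme '%s': %d ecosystem types (%d biomes)\n",
              object@schemeName, length(object@typeLabels), object@nBiomes))
})

#' Per-cell presence, area and coverage at one year
#'
#' For a single cell and year, returns per-type presence (1 if the type's area
#' exceeds `presenceThreshold`), area (km^2) and coverage (fraction of the
#' cell's land area, summing to 1).
#'
#' @param grid A [LandUseGrid-class].
#' @param cell Cell index (1-based row index).
#' @param year Calendar year present in `gridYears(grid)`.
#' @param presenceThreshold Minimum area (km^2) for a type to count as
#'   present; the default 0 counts any strictly positive area.
#' @return List with numeric vectors `presence`, `area`, `coverage`, named by
#'   type.
#' @export
cellState <- function(grid, cell, year, presenceThreshold = 0) {
  stopifnot(is(grid, "LandUseGrid"))
  yi <- match(year, gridYears(grid))
  if (is.na(yi)) .err("ecodivParameterError", "year %s not in grid", year)
  if (cell < 1 || cell > nrow(grid)) {
    .err("ecodivParameterError", "cell index out of range")
  }
  la <- landArea(grid)[cell]
  if (la <= 0) {
    .err("ecodivExcludedCell", "cell %d has no land area; excluded", cell)
  }
  area <- vapply(as.list(assays(grid)), function(a) a[cell, yi], numeric(1)) *
    cellArea(grid)[cell]
  list(
    presence = as.integer(area > presenceThreshold),
    area = area,
    coverage = area / la
  )
}

# Coverage matrix (cells x types) at one year index; rows without land are NA.
.coverageAt <- function(grid, yearIdx) {
  m <- vapply(as.list(assays(grid)), function(a) a[, yearIdx], numeric(nrow(grid)))
  m <- matrix(m, nrow = nrow(grid),
              dimnames = list(NULL, typeLabels(grid)))
  landFrac <- landArea(grid) / cellArea(grid)
  cov <- m / landFrac
  cov[landFrac <= 0, ] <- NA_real_
  cov
}

# Area matrix (cells x types) at one year index.
.areaAt <- function(grid, yearIdx) {
  m <- vapply(as.list(assays(grid)), function(a) a[, yearIdx], numeric(nrow(grid)))
  matrix(m * cellArea(grid), nrow = nrow(grid),
         dimnames = list(NULL, typeLabels(grid)))
}

# Group consecutive year indices whose fraction maps are identical, so
# window statistics can be computed once per distinct state and weighted by
# run length. Synthetic LUH2-like data are piecewise constant within
# centuries (pre-onset) and decades (post-onset), making this exact and fast.
.distinctYearGroups <- function(grid, yearIdx) {
  if (length(yearIdx) == 1L) {
    return(list(rep = yearIdx, weight = 1))
  }
  as <- as.list(assays(grid))
  changed <- vapply(seq_along(yearIdx)[-1L], function(k) {
    a <- yearIdx[k - 1L]
    b <- yearIdx[k]
    for (m in as) {
      if (any(m[, a] != m[, b])) return(TRUE)
    }
    FALSE
  }, logical(1))
  grp <- cumsum(c(TRUE, changed))
  list(
    rep = yearIdx[!duplicated(grp)],
    weight = as.numeric(tabulate(grp))
  )
}
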