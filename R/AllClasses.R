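#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assays assay rowData
#'   rowData<- colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# The 12 LUH2 "states" fraction layers, in canonical order.
.LUH2_TYPES <- c(
  "primf", "primn", "secdf", "secdn", "pastr", "range", "urban",
  "c3ann", "c3per", "c4ann", "c4per", "c3nfx"
)

#' Container for gridded fractional land-use/ecosystem histories
#'
#' `LandUseGrid` extends [SummarizedExperiment::SummarizedExperiment]: rows are
#' grid cells (row-major from the south-west corner, x fastest), columns are
#' calendar years, and there is one assay per land-use or ecosystem type
#' holding the fraction of each cell's *total* area occupied by that type.
#' Cell geometry lives in `metadata()` (`gridType`, projected `xEdges`,
#' `yEdges` in km, and for lon-lat grids also `lonEdges`/`latEdges` in
#' degrees); per-cell `cellArea` and `landArea` (km^2) live in `rowData()`,
#' as do `biomeId`, `regionId` and `isBoundary` once [overlayZones()] has run.
#'
#' The class invariant ("closure") is that for every cell and year the type
#' fractions sum to the cell's land fraction `landArea/cellArea` within 1e-8.
#'
#' @export
setClass("LandUseGrid", contains = "SummarizedExperiment")

setValidity("LandUseGrid", function(object) {
  md <- metadata(object)
  need <- c("gridType", "xEdges", "yEdges", "nx", "ny")
  if (!all(need %in% names(md))) {
    return(paste("metadata must contain", paste(need, collapse = ", ")))
  }
  if (!md$gridType %in% c("lonlat", "equalarea")) {
    return("gridType must be 'lonlat' or 'equalarea'")
  }
  if (nrow(object) != md$nx * md$ny) return("nrow must equal nx * ny")
  rd <- rowData(object)
  if (!all(c("cellArea", "landArea") %in% colnames(rd))) {
    return("rowData must contain cellArea and landArea")
  }
  if (any(rd$cellArea <= 0)) return("cellArea must be positive")
  if (any(rd$landArea < -1e-9) || any(rd$landArea > rd$cellArea * (1 + 1e-6))) {
    return("landArea must lie in [0, cellArea]")
  }
  if (length(assays(object)) == 0L) return("at least one type assay required")
  if (is.null(names(assays(object)))) return("assays must be named by type")
  tot <- 0
  for (a in as.list(assays(object))) {
    if (!is.matrix(a) || nrow(a) != nrow(object) || ncol(a) != ncol(object)) {
      return("all assays must be cells x years matrices")
    }
    if (any(a < -1e-9) || any(a > 1 + 1e-9)) {
      return("fractions must lie in [0, 1]")
    }
    tot <- tot + a
  }
  landFrac <- rd$landArea / rd$cellArea
  if (max(abs(tot - landFrac)) > 1e-8) {
    return("type fractions must sum to the cell land fraction (closure)")
  }
  if (!"year" %in% colnames(colData(object))) return("colData must contain year")
  TRUE
})

#' Construct a LandUseGrid
#'
#' @param fractions Named list of cells x years matrices, one per type, each
#'   entry the fraction of the cell's total area covered by that type.
#' @param years Integer vector of calendar years (one per column).
#' @param xEdges,yEdges Projected cell edges (km) in the cylindrical equal-area
#'   working projection; lengths `nx + 1` and `ny + 1`.
#' @param landArea Per-cell land area in km^2. If `NULL`, computed from the
#'   fraction closure (sum of type fractions times cell area at year 1).
#' @param gridType `"lonlat"` for 0.25-degree-style source grids or
#'   `"equalarea"` for regridded/aggregated grids.
#' @param lonEdges,latEdges Edges in degrees (lon-lat grids only).
#' @return A [LandUseGrid-class] object.
#' @export
LandUseGrid <- function(fractions, years, xEdges, yEdges, landArea = NULL,
                        gridType = c("lonlat", "equalarea"),
                        lonEdges = NULL, latEdges = NULL) {
  gridType <- match.arg(gridType)
  if (!is.list(fractions) || is.null(names(fractions))) {
    .err("ecodivParameterError", "'fractions' must be a named list of matrices")
  }
  nx <- length(xEdges) - 1L
  ny <- length(yEdges) - 1L
  n <- nx * ny
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  w <- diff(xEdges)
  h <- diff(yEdges)
  cellArea <- w[ix] * h[iy]
  xc <- (xEdges[-1L] + xEdges[-(nx + 1L)]) / 2
  yc <- (yEdges[-1L] + yEdges[-(ny + 1L)]) / 2
  fractions <- lapply(fractions, function(a) {
    a <- as.matrix(a)
    dimnames(a) <- NULL
    a
  })
  if (is.null(landArea)) {
    landArea <- Reduce(`+`, lapply(fractions, function(a) a[, 1L])) * cellArea
  }
  rd <- DataFrame(
    ix = ix, iy = iy,
    x = xc[ix], y = yc[iy],
    lon = .invProjLon(xc[ix]), lat = .invProjLat(yc[iy]),
    cellArea = cellArea, landArea = as.numeric(landArea)
  )
  rownames(rd) <- sprintf("cell%05d", seq_len(n) - 1L)
  se <- SummarizedExperiment(
    assays = fractions,
    rowData = rd,
    colData = DataFrame(year = as.integer(years), row.names = as.character(years))
  )
  md <- list(gridType = gridType, xEdges = xEdges, yEdges = yEdges,
             nx = nx, ny = ny)
  if (gridType == "lonlat") {
    md$lonEdges <- lonEdges
    md$latEdges <- latEdges
  }
  metadata(se) <- md
  new("LandUseGrid", se)
}

#' Synthetic-scenario parameters
#'
#' Parameters of the seeded land-use history generator. The grid is `nLon` x
#' `nLat` cells of 0.25 degrees centred on (`lonOrigin`, `latOrigin`) offsets;
#' anthropogenic conversion runs at `0.1 * expansionRate` per year before
#' `anthroOnsetYear` and at `expansionRate` after it, converting primary
#' vegetation first (then secondary once primary is nearly exhausted);
#' `noiseSd` is the standard deviation of logit-scale observation noise
#' applied per temporal block and renormalized to closure.
#'
#' @export
setClass("ScenarioParams", representation(
  nLon = "integer", nLat = "integer",
  yearStart = "integer", yearEnd = "integer",
  landFractionMap = "numeric",
  anthroOnsetYear = "integer",
  expansionRate = "numeric", noiseSd = "numeric",
  nBiomes = "integer", nRegions = "integer",
  seed = "integer",
  lonOrigin = "numeric", latOrigin = "numeric"
))

setValidity("ScenarioParams", function(object) {
  if (object@nLon < 1L || object@nLat < 1L) return("grid dimensions must be >= 1")
  if (object@yearStart >= object@yearEnd) return("yearStart must be < yearEnd")
  if (length(object@landFractionMap) &&
      length(object@landFractionMap) != object@nLon * object@nLat) {
    return("landFractionMap must have nLon * nLat entries")
  }
  if (length(object@landFractionMap) &&
      (any(object@landFractionMap < 0) || any(object@landFractionMap > 1))) {
    return("landFractionMap values must lie in [0, 1]")
  }
  if (object@expansionRate < 0) return("expansionRate must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@nBiomes < 1L || object@nRegions < 1L) return("zone counts must be >= 1")
  if (object@nBiomes > object@nLon) return("more biomes than grid columns")
  if (object@nRegions > object@nLat) return("more regions than grid rows")
  TRUE
})

#' @param nLon,nLat Grid dimensions in cells (0.25-degree cells).
#' @param yearStart,yearEnd Calendar years CE spanned by the history.
#' @param landFractionMap Optional per-cell land fraction in `[0, 1]`
#'   (row-major from the south-west corner); drawn from the seed if `NULL`.
#' @param anthroOnsetYear Year CE when anthropogenic expansion accelerates and
#'   the temporal resolution switches from centurial to decadal blocks.
#' @param expansionRate Post-onset fractional conversion rate of remaining
#'   natural stock per year (dimensionless / yr).
#' @param noiseSd Standard deviation of logit-scale fraction noise per block.
#' @param nBiomes,nRegions Number of biome and region zones.
#' @param seed Integer RNG seed.
#' @param lonOrigin,latOrigin South-west corner in degrees; defaults centre
#'   the grid on (0, 0).
#' @rdname ScenarioParams-class
#' @export
ScenarioParams <- function(nLon = 36, nLat = 18, yearStart = 900, yearEnd = 2000,
                           landFractionMap = NULL, anthroOnsetYear = 1700,
                           expansionRate = 0.003, noiseSd = 0.1,
                           nBiomes = 14, nRegions = 17, seed = 1L,
                           lonOrigin = NULL, latOrigin = NULL) {
  if (is.null(lonOrigin)) lonOrigin <- -0.125 * nLon
  if (is.null(latOrigin)) latOrigin <- -0.125 * nLat
  obj <- try(new("ScenarioParams",
    nLon = as.integer(nLon), nLat = as.integer(nLat),
    yearStart = as.integer(yearStart), yearEnd = as.integer(yearEnd),
    landFractionMap = if (is.null(landFractionMap)) numeric(0) else as.numeric(landFractionMap),
    anthroOnsetYear = as.integer(anthroOnsetYear),
    expansionRate = as.numeric(expansionRate), noiseSd = as.numeric(noiseSd),
    nBiomes = as.integer(nBiomes), nRegions = as.integer(nRegions),
    seed = as.integer(seed),
    lonOrigin = as.numeric(lonOrigin), latOrigin = as.numeric(latOrigin)
  ), silent = TRUE)
  if (inherits(obj, "try-error")) {
    .err("ecodivParameterError", "invalid scenario parameters: %s",
         attr(obj, "condition")$message)
  }
  obj
}

#' Biome and region zone maps on a rectangular grid
#'
#' Integer biome and region labels per cell of an axis-aligned grid given by
#' projected edges (same conventions as [LandUseGrid()]).
#'
#' @export
setClass("ZoneMaps", representation(
  biome = "integer", region = "integer",
  xEdges = "numeric", yEdges = "numeric"
))

setValidity("ZoneMaps", function(object) {
  n <- (length(object@xEdges) - 1L) * (length(object@yEdges) - 1L)
  if (length(object@biome) != n || length(object@region) != n) {
    return("biome and region must have one label per cell")
  }
  if (any(is.na(object@biome)) || any(is.na(object@region))) {
    return("zone labels must not be NA")
  }
  TRUE
})

#' @param biome,region Integer label vectors, row-major from the south-west.
#' @param xEdges,yEdges Projected cell edges in km.
#' @rdname ZoneMaps-class
#' @export
ZoneMaps <- function(biome, region, xEdges, yEdges) {
  new("ZoneMaps", biome = as.integer(biome), region = as.integer(region),
      xEdges = as.numeric(xEdges), yEdges = as.numeric(yEdges))
}

#' Ecosystem classification scheme
#'
#' Total mapping from (LUH2 land-use layer, biome) to ecosystem type id.
#' `biome = NA` rows apply to every biome. Built-in schemes:
#' `base9` (9 types, biome-independent), `natural_x_biome`
#' (4 natural types crossed with biomes + 5 global anthropogenic types) and
#' `all_x_biome` (all 9 types crossed with biomes).
#'
#' @export
setClass("ClassificationScheme", representation(
  schemeName = "character", nBiomes = "integer",
  mapping = "data.frame", typeLabels = "character"
))

setValidity("ClassificationScheme", function(object) {
  m <- object@mapping
  if (!all(c("landUse", "biome", "ecosystemType") %in% names(m))) {
    return("mapping needs landUse, biome, ecosystemType columns")
  }
  if (!setequal(unique(m$landUse), .LUH2_TYPES)) {
    return("mapping must cover exactly the 12 LUH2 land-use layers")
  }
  if (!setequal(unique(m$ecosystemType), object@typeLabels)) {
    return("typeLabels must match the mapping's ecosystem types")
  }
  TRUE
})

#' Equal-area target grid specification
#'
#' @param targetCellArea Target cell area in km^2 (about 769 for the
#'   0.25-degree-equivalent grid).
#' @param grainFactor Linear aggregation factor for coarse-grain analyses.
#' @export
GridSpec <- function(targetCellArea = 769, grainFactor = 1L) {
  new("GridSpec", targetCellArea = as.numeric(targetCellArea),
      grainFactor = as.integer(grainFactor))
}

#' @rdname GridSpec
#' @export
setClass("GridSpec", representation(
  targetCellArea = "numeric", grainFactor = "integer"
))

setValidity("GridSpec", function(object) {
  if (object@targetCellArea <= 0) return("targetCellArea must be positive")
  if (object@grainFactor < 1L) return("grainFactor must be >= 1")
  TRUE
})
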