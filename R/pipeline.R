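# End-to-end orchestration of the two analysis tracks: alpha-diversity trends
# and beta-diversity trends, driven by a declarative configuration list.

# Fill in defaults and validate a run configuration.
.normalizeConfig <- function(config) {
  if (!is.list(config)) .err("ecodivParameterError", "config must be a list")
  hasScenario <- !is.null(config$scenario)
  hasPath <- !is.null(config$landUsePath)
  if (hasScenario == hasPath) {
    .err("ecodivParameterError",
         "provide exactly one of 'scenario' and 'landUsePath'")
  }
  if (hasScenario && !is(config$scenario, "ScenarioParams")) {
    config$scenario <- do.call(ScenarioParams, config$scenario)
  }
  defaults <- list(
    targetCellArea = 769,
    scheme = "base9",
    seed = 1L,
    bootstrapDraws = 1000L,
    sampleFraction = 0.01,
    betaDraws = 100L,
    grainFactors = c(1L, 4L),
    outDir = NULL
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

# Shared front end: generate or read the source grid, regrid to equal area,
# overlay zones and classify. Returns the classified grid plus bookkeeping.
.prepareGrid <- function(config) {
  if (!is.null(config$scenario)) {
    src <- generateHistory(config$scenario)
    zones <- generateZoneMaps(config$scenario)
    nBiomes <- config$scenario@nBiomes
  } else {
    src <- readLandUseGrid(config$landUsePath)
    zones <- config$zones
    if (is.null(zones)) {
      .err("ecodivParameterError", "file input requires a 'zones' ZoneMaps object")
    }
    nBiomes <- max(zones@biome)
  }
  eq <- regridEqualArea(src, GridSpec(targetCellArea = config$targetCellArea))
  eq <- overlayZones(eq, zones)
  scheme <- classificationScheme(config$scheme, nBiomes = nBiomes)
  classified <- applyScheme(eq, scheme)
  list(grid = classified, scheme = scheme,
       nRemoved = sum(rowData(eq)$isBoundary),
       nRetained = sum(retainedCells(eq)))
}

# Default centurial + decadal window sets for a span and onset year.
.defaultWindowSets <- function(config) {
  if (!is.null(config$windows)) return(config$windows)
  sc <- config$scenario
  if (is.null(sc)) {
    .err("ecodivParameterError", "explicit 'windows' required for file input")
  }
  w <- list(centurial = makeWindows(sc@yearStart, sc@yearEnd, 100))
  if (sc@anthroOnsetYear < sc@yearEnd) {
    w$decadal <- makeWindows(sc@anthroOnsetYear, sc@yearEnd, 10)
  }
  w
}

#' Run the alpha-diversity analysis track
#'
#' Orchestrates the full alpha pipeline: synthetic-history generation (or
#' NetCDF input), equal-area regridding, zone overlay with boundary-cell
#' removal, classification, the five per-cell diversity metrics, window
#' averaging with net change against the first window, land-area-weighted
#' global/regional/biome means, and a region-stratified bootstrap of the
#' global mean with interdecile bands.
#'
#' @param config Named list. Fields (with defaults): `scenario`
#'   ([ScenarioParams-class] or argument list) *or* `landUsePath` plus
#'   `zones`; `scheme` (`"base9"`); `targetCellArea` (769 km^2); `windows`
#'   (list of [makeWindows()] tables; default centurial over the span plus
#'   decadal from the onset year); `bootstrapDraws` (1000); `sampleFraction`
#'   (0.01 of retained cells per draw); `seed` (1, for the bootstrap);
#'   `outDir` (write CSVs when set).
#' @return List with `summary` (long table: scope, group_id, metric,
#'   window_midpoint, value, net_change, decile_1, decile_9, n_cells, series,
#'   seed, config_hash), `cells` (per-cell window means, long), and `counts`
#'   (cells removed/retained). Written to `alpha_summary.csv` /
#'   `alpha_cells.csv` when `outDir` is set.
#' @export
runAlpha <- function(config) {
  config <- .normalizeConfig(config)
  hash <- .configHash(config)
  prep <- .prepareGrid(config)
  grid <- prep$grid
  d <- if (config$scheme == "base9") defaultDissimilarityMatrix() else NULL
  if (!is.null(config$dissimilarity)) d <- config$dissimilarity
  alpha <- alphaDiversity(grid, dissimilarity = d)
  keep <- which(retainedCells(grid))
  rd <- rowData(grid)
  weights <- landArea(grid)[keep]
  region <- rd$regionId[keep]
  biome <- rd$biomeId[keep]
  years <- gridYears(grid)
  windowSets <- .defaultWindowSets(config)

  summaryRows <- list()
  cellRows <- list()
  for (series in names(windowSets)) {
    windows <- windowSets[[series]]
    for (metric in names(alpha)) {
      wm <- windowMean(alpha[[metric]][keep, , drop = FALSE], years, windows)
      nc <- netChange(wm)
      boot <- bootstrapMeans(
        wm, weights, region,
        nSample = max(2L, round(config$sampleFraction * length(keep))),
        nDraws = config$bootstrapDraws, seed = config$seed
      )
      addScope <- function(scope, groups) {
        gm <- weightedSpatialMean(wm, weights, groups)
        gn <- weightedSpatialMean(nc, weights, groups)
        data.frame(
          scope = scope,
          group_id = rep(rownames(gm), ncol(gm)),
          metric = metric,
          window_midpoint = rep(windows$midpoint, each = nrow(gm)),
          value = as.vector(gm),
          net_change = as.vector(gn),
          decile_1 = if (scope == "global") rep(boot$decile1, each = nrow(gm)) else NA_real_,
          decile_9 = if (scope == "global") rep(boot$decile9, each = nrow(gm)) else NA_real_,
          n_cells = as.vector(vapply(seq_len(ncol(wm)), function(w) {
            vapply(rownames(gm), function(g) {
              rows <- if (scope == "global") seq_len(nrow(wm)) else which(groups == g)
              sum(!is.na(wm[rows, w]))
            }, 1L)
          }, integer(nrow(gm)))),
          series = series
        )
      }
      summaryRows[[length(summaryRows) + 1L]] <- addScope("global", NULL)
      summaryRows[[length(summaryRows) + 1L]] <- addScope("region", as.character(region))
      summaryRows[[length(summaryRows) + 1L]] <- addScope("biome", as.character(biome))
      cellRows[[length(cellRows) + 1L]] <- data.frame(
        cell_id = rep(keep - 1L, ncol(wm)),
        metric = metric,
        series = series,
        window_midpoint = rep(windows$midpoint, each = nrow(wm)),
        value = as.vector(wm),
        net_change = as.vector(nc)
      )
    }
  }
  summary <- do.call(rbind, summaryRows)
  summary$seed <- config$seed
  summary$config_hash <- hash
  cells <- do.call(rbind, cellRows)
  res <- list(summary = summary, cells = cells,
              counts = c(removed_boundary = prep$nRemoved,
                         retained = prep$nRetained))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(config$outDir, "alpha_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(cells, file.path(config$outDir, "alpha_cells.csv"),
                     row.names = FALSE)
  }
  res
}

#' Run the beta-diversity analysis track
#'
#' Orchestrates the beta pipeline: prepared classified grid (as in
#' [runAlpha()]), then for each design row — a grain factor plus an extent
#' (window factor or global) — the mean pairwise dissimilarity time series
#' for both the Jaccard and Bray-Curtis families, with decompositions, net
#' change against the first window, and draw interdecile bands where the pair
#' universe is subsampled.
#'
#' @param config As in [runAlpha()], plus optional `designs`: a `data.frame`
#'   with columns `grain` (integer factor), `extent` (`"global"` or an integer
#'   factor in grain-cell units) and `sampled` (logical; subsample with
#'   `betaDraws` draws of `sampleFraction` of cells). The default runs grain 1
#'   at global extent (sampled) and within 4x4-cell extents (exhaustive), and
#'   grain 4 at global extent (exhaustive).
#' @return List with `summary` (long table over grain, extent, index,
#'   component, window) and `counts`. Written to `beta_summary.csv` when
#'   `outDir` is set.
#' @export
runBeta <- function(config) {
  config <- .normalizeConfig(config)
  hash <- .configHash(config)
  prep <- .prepareGrid(config)
  windowSets <- .defaultWindowSets(config)
  designs <- config$designs
  if (is.null(designs)) {
    designs <- data.frame(
      grain = c(1L, 1L, 4L),
      extent = c("global", "4", "global"),
      sampled = c(TRUE, FALSE, FALSE)
    )
  }
  rows <- list()
  for (i in seq_len(nrow(designs))) {
    grid <- aggregateGrain(prep$grid, designs$grain[i])
    nRet <- sum(retainedCells(grid))
    extent <- designs$extent[i]
    extentFactor <- if (identical(extent, "global")) NULL else as.integer(extent)
    sampled <- isTRUE(designs$sampled[i]) && nRet > 3L
    nDraws <- if (sampled) config$betaDraws else 1L
    sampleSize <- if (sampled) {
      max(2L, round(config$sampleFraction * nRet))
    } else NULL
    for (series in names(windowSets)) {
      for (index in c("jaccard", "braycurtis")) {
        ts <- betaTimeseries(
          grid, windowSets[[series]], index = index,
          extentFactor = extentFactor, nDraws = nDraws,
          sampleSize = sampleSize, seed = config$seed
        )
        ts$grain <- designs$grain[i]
        ts$extent <- extent
        ts$series <- series
        rows[[length(rows) + 1L]] <- ts
      }
    }
  }
  summary <- do.call(rbind, rows)
  summary$seed <- config$seed
  summary$config_hash <- hash
  res <- list(summary = summary,
              counts = c(removed_boundary = prep$nRemoved,
                         retained = prep$nRetained))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(config$outDir, "beta_summary.csv"),
                     row.names = FALSE)
  }
  res
}
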