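test_that("LUH2 states NetCDF round trip reproduces the grid", {
  p <- smallParams(yearStart = 1999, yearEnd = 2001, noiseSd = 0.1, seed = 4)
  g <- generateHistory(p)
  path <- withr::local_tempfile(fileext = ".nc")
  writeLUH2States(g, path)
  g2 <- readLandUseGrid(path)
  expect_equal(gridYears(g2), gridYears(g))
  expect_length(gridYears(g2), 3L)
  for (t in typeLabels(g)) {
    expect_lt(max(abs(SummarizedExperiment::assay(g2, t) -
                        SummarizedExperiment::assay(g, t))), 1e-9)
  }
  # ocean cells hold zeros in all 12 variables
  ocean <- which(landArea(g) == 0)
  if (length(ocean)) {
    tot <- Reduce(`+`, as.list(SummarizedExperiment::assays(g2)))
    expect_true(all(tot[ocean, ] == 0))
  }
  # the written schema carries exactly the 12 states variables
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  expect_setequal(names(nc$var),
                  c("primf", "primn", "secdf", "secdn", "pastr", "range",
                    "urban", "c3ann", "c3per", "c4ann", "c4per", "c3nfx"))
})

test_that("a file lacking a states variable is a schema error", {
  p <- smallParams(yearStart = 2000, yearEnd = 2001)
  g <- generateHistory(p)
  path <- withr::local_tempfile(fileext = ".nc")
  writeLUH2States(g, path)
  nc <- ncdf4::nc_open(path)
  keepVars <- setdiff(names(nc$var), "pastr")
  path2 <- withr::local_tempfile(fileext = ".nc")
  dims <- nc$var[[keepVars[1]]]$dim
  vars <- lapply(keepVars, function(v) ncdf4::ncvar_def(v, "1", dims, prec = "double"))
  nc2 <- ncdf4::nc_create(path2, vars)
  for (v in keepVars) ncdf4::ncvar_put(nc2, v, ncdf4::ncvar_get(nc, v, collapse_degen = FALSE))
  ncdf4::nc_close(nc2)
  ncdf4::nc_close(nc)
  expect_error(readLandUseGrid(path2), class = "ecodivSchemaError")
  expect_error(readLandUseGrid(withr::local_tempfile(fileext = ".nc")),
               class = "ecodivIOError")
})

test_that("regridding an equal-area grid onto itself is the identity", {
  g <- generateHistory(smallParams(seed = 8))
  eq <- regridEqualArea(g, GridSpec(769))
  area <- cellArea(eq)[1]
  eq2 <- regridEqualArea(eq, GridSpec(area))
  expect_equal(metadata(eq2)$nx, metadata(eq)$nx)
  for (t in typeLabels(eq)) {
    expect_lt(max(abs(SummarizedExperiment::assay(eq2, t) -
                        SummarizedExperiment::assay(eq, t))), 1e-9)
  }
})

test_that("a uniform source map regrids to a uniform target map", {
  n <- 12 * 8
  years <- 1:2
  fr <- c(list(primf = matrix(1, n, 2)),
          lapply(setNames(ecodivgrid:::.LUH2_TYPES[-1],
                          ecodivgrid:::.LUH2_TYPES[-1]),
                 function(t) matrix(0, n, 2)))
  lonE <- 0.25 * (0:12)
  latE <- 0.25 * (0:8)
  g <- LandUseGrid(fr, years, xEdges = ecodivgrid:::.projX(lonE),
                   yEdges = ecodivgrid:::.projY(latE), gridType = "lonlat",
                   lonEdges = lonE, latEdges = latE)
  eq <- regridEqualArea(g, GridSpec(769))
  a <- SummarizedExperiment::assay(eq, "primf")
  expect_lt(max(abs(a - 1)), 1e-9)
  # all target cells share one exact area
  expect_lt(diff(range(cellArea(eq))), 1e-9)
})

test_that("regridding conserves global area per type and year", {
  g <- generateHistory(smallParams(nLon = 10, nLat = 10, noiseSd = 0.2, seed = 13))
  eq <- regridEqualArea(g, GridSpec(500))
  for (t in typeLabels(g)) {
    before <- colSums(SummarizedExperiment::assay(g, t) * cellArea(g))
    after <- colSums(SummarizedExperiment::assay(eq, t) * cellArea(eq))
    expect_lt(max(abs(after - before) / pmax(before, 1e-12)), 1e-6, label = t)
  }
  expect_lt(abs(sum(landArea(eq)) - sum(landArea(g))) / sum(landArea(g)), 1e-9)
})

test_that("zone overlay flags biome-boundary cells exactly when a divide crosses a cell", {
  p <- smallParams(nBiomes = 1, nRegions = 1, yearStart = 1998, yearEnd = 2000)
  g <- generateHistory(p)
  md <- metadata(g)
  # single-biome world: nothing flagged
  suppressMessages(g1 <- overlayZones(g, generateZoneMaps(p)))
  expect_equal(sum(rowData(g1)$isBoundary), 0L)
  # two biomes split exactly on a cell edge: still nothing flagged
  nLon <- p@nLon
  xr <- range(md$xEdges)
  yr <- range(md$yEdges)
  zEdgeAligned <- ZoneMaps(
    biome = 1:2, region = c(1L, 1L),
    xEdges = c(xr[1], md$xEdges[nLon / 2 + 1], xr[2]), yEdges = yr
  )
  suppressMessages(g2 <- overlayZones(g, zEdgeAligned))
  expect_equal(sum(rowData(g2)$isBoundary), 0L)
  expect_true(all(rowData(g2)$biomeId %in% 1:2))
  # the divide shifted half a cell west: exactly one column flagged
  zShifted <- ZoneMaps(
    biome = 1:2, region = c(1L, 1L),
    xEdges = c(xr[1], md$xEdges[nLon / 2 + 1] - 0.5 * diff(md$xEdges[1:2]), xr[2]),
    yEdges = yr
  )
  suppressMessages(g3 <- overlayZones(g, zShifted))
  flaggedCols <- unique(rowData(g3)$ix[rowData(g3)$isBoundary])
  expect_equal(flaggedCols, nLon / 2L)
  # a zone map that fails to cover the grid is a coverage error
  zPartial <- ZoneMaps(biome = 1L, region = 1L,
                       xEdges = c(xr[1], mean(xr)), yEdges = yr)
  expect_error(suppressMessages(overlayZones(g, zPartial)),
               class = "ecodivCoverageError")
})

test_that("grain aggregation sums block areas and composes", {
  # 2x2 fine block with 10 km^2 of cropland in one corner
  side <- sqrt(769)
  fr <- lapply(setNames(ecodivgrid:::.LUH2_TYPES, ecodivgrid:::.LUH2_TYPES),
               function(t) matrix(0, 4, 1))
  fr$c3ann <- matrix(c(10 / side^2, 0, 0, 0), 4, 1)
  g <- LandUseGrid(fr, years = 2000, xEdges = side * (0:2), yEdges = side * (0:2),
                   gridType = "equalarea")
  cg <- aggregateGrain(g, 2L)
  expect_equal(nrow(cg), 1L)
  expect_equal(SummarizedExperiment::assay(cg, "c3ann")[1, 1] * cellArea(cg)[1], 10)
  expect_identical(aggregateGrain(g, 1L), g)
  expect_error(aggregateGrain(g, 0L), class = "ecodivParameterError")

  # composition and conservation on a generated world
  w <- generateHistory(smallParams(nLon = 8, nLat = 8, noiseSd = 0.2, seed = 21,
                                   yearStart = 1990, yearEnd = 2000))
  eq <- regridEqualArea(w, GridSpec(769))
  g4 <- aggregateGrain(eq, 4L)
  g22 <- aggregateGrain(aggregateGrain(eq, 2L), 2L)
  for (t in typeLabels(eq)) {
    a4 <- SummarizedExperiment::assay(g4, t) * cellArea(g4)
    a22 <- SummarizedExperiment::assay(g22, t) * cellArea(g22)
    expect_lt(max(abs(a4 - a22)), 1e-9, label = t)
    before <- colSums(SummarizedExperiment::assay(eq, t) * cellArea(eq))
    expect_lt(max(abs(colSums(a4) - before) / pmax(before, 1e-12)), 1e-6, label = t)
  }
  # a coarse cell is at least as rich as its richest fine cell
  alphaF <- alphaDiversity(eq)
  alphaC <- alphaDiversity(g4)
  rdF <- rowData(eq)
  coarseOf <- (rdF$ix - 1) %/% 4 + 1 + ((rdF$iy - 1) %/% 4) * metadata(g4)$nx
  land <- landArea(eq) > 0
  for (cc in unique(coarseOf[land])) {
    fine <- which(coarseOf == cc & land)
    expect_gte(alphaC$richness[cc, 1], max(alphaF$richness[fine, 1]))
  }
})

test_that("cellState reports presence, area and coverage arithmetic", {
  side <- sqrt(769)
  landFrac <- 400 / side^2
  fr <- lapply(setNames(ecodivgrid:::.LUH2_TYPES, ecodivgrid:::.LUH2_TYPES),
               function(t) matrix(0, 2, 1))
  fr$c3ann <- matrix(c(300 / side^2, 0), 2, 1)
  fr$primf <- matrix(c(100 / side^2, 0), 2, 1)
  g <- LandUseGrid(fr, years = 2000, xEdges = side * (0:2), yEdges = c(0, side),
                   gridType = "equalarea")
  st <- cellState(g, 1, 2000)
  expect_equal(unname(st$coverage[c("c3ann", "primf")]), c(0.75, 0.25))
  expect_equal(sum(st$coverage), 1, tolerance = 1e-9)
  expect_equal(unname(st$presence), as.integer(st$area > 0))
  expect_equal(sum(st$presence), 2L)
  expect_error(cellState(g, 2, 2000), class = "ecodivExcludedCell")
})
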