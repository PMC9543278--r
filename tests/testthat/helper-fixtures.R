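# Shared fixtures: small scenario parameter sets and hand-built grids.

smallParams <- function(..., nLon = 12, nLat = 8, yearStart = 1500,
                        yearEnd = 1800, anthroOnsetYear = 1700,
                        nBiomes = 3, nRegions = 4, seed = 11) {
  ScenarioParams(nLon = nLon, nLat = nLat, yearStart = yearStart,
                 yearEnd = yearEnd, anthroOnsetYear = anthroOnsetYear,
                 nBiomes = nBiomes, nRegions = nRegions, seed = seed, ...)
}

# Hand-built single-row equal-area grid from a named list of cells x years
# fraction matrices; the land fraction is the per-cell sum of fractions
# (must be constant over years).
toyGrid <- function(fractions, years = seq_len(ncol(fractions[[1]]))) {
  n <- nrow(fractions[[1]])
  side <- sqrt(769)
  LandUseGrid(fractions, years = years,
              xEdges = side * (0:n), yEdges = c(0, side),
              gridType = "equalarea")
}

# Random valid composition over E types (positive, summing to 1).
randomComposition <- function(E) {
  p <- stats::rgamma(E, shape = 1) + 1e-12
  p / sum(p)
}
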