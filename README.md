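# ecodivgrid

Millennium-scale trends in the diversity of *ecosystem types*, computed from
gridded annual fractional land-use histories in the LUH2 "states" schema
(12 land-use fraction layers per 0.25° cell per year).

The package treats each grid cell as a small community of ecosystem types and
applies community-ecology diversity statistics to it:

* **α diversity per cell**: richness *E*; Shannon *H′ = −Σ pᵢ log pᵢ*;
  Pielou *J = H′/log E* (defined for *E* ≥ 2); Gini–Simpson *D = 1 − Σ pᵢ²*;
  and Rao's quadratic entropy *Q = Σᵢ Σⱼ d_ij pᵢ pⱼ*, where *pᵢ* is the share
  of the cell's land covered by type *i* and *d_ij* ∈ [0, 1] is a
  compositional dissimilarity between types built from a 1 − Sørensen source
  table (`buildDissimilarityMatrix()`).
* **β diversity between cells**: Jaccard dissimilarity decomposed into
  turnover + nestedness, and Bray–Curtis into balanced variation + abundance
  gradient (Baselga partitions), averaged over all qualifying pairs within a
  grain × extent design, `β̄ = Σ p_k,i / N`, with optional subsampled draws.
* **Temporal machinery**: centurial (900–999 → midpoint 950, …) and decadal
  (1700–1709 → 1705, …) window means; net change against the first window;
  land-area-weighted global/regional means; a region-stratified bootstrap
  (1000 draws, 1% of cells) summarized by interdecile bands, with a
  non-overlap significance rule; presence persistence of a type between two
  windows.

Infrastructure: a `SummarizedExperiment`-based `LandUseGrid` container,
NetCDF I/O in the LUH2 "states" dialect (`ncdf4`), exact equal-area
regridding with area-conserving reapportionment, biome/region overlay with
boundary-cell removal, block aggregation to coarser grains, three
classification schemes (9 / 61 / 126 ecosystem types), and a seeded synthetic
scenario generator so everything runs and is tested without downloads.

## Worked example

```r
library(ecodivgrid)

params <- ScenarioParams(nLon = 16, nLat = 10, yearStart = 900, yearEnd = 2000,
                         nBiomes = 4, nRegions = 5, seed = 3)
grid  <- generateHistory(params)            # 12-layer LUH2-like history
zones <- generateZoneMaps(params)
eq    <- regridEqualArea(grid, GridSpec(769))
eq    <- overlayZones(eq, zones)            # flags biome-boundary cells
cl    <- applyScheme(eq, classificationScheme("base9", 4))

alpha <- alphaDiversity(cl, defaultDissimilarityMatrix())
w     <- makeWindows(900, 2000, 100)        # 11 centurial windows
keep  <- which(retainedCells(cl))
wm    <- windowMean(alpha$richness[keep, ], gridYears(cl), w)
round(weightedSpatialMean(wm, landArea(cl)[keep]), 2)
#>        950 1050 1150 1250 1350 1450 1550 1650 1750 1850 1950
#> global 5.78 6.84 7.13 7.37  7.5 7.63 7.75 7.84 8.33 8.65 8.72
```

The land-area-weighted global mean number of ecosystem types per ~769 km²
cell rises from 5.78 in the 10th century to 8.72 in the 20th on this
synthetic expansion scenario: converting primary vegetation adds
anthropogenic types faster than it removes natural ones. The same run's β
track shows the two signatures of interest — presence-based Jaccard β̄ at
global extent ends below its 10th-century baseline (homogenization: the same
anthropogenic types appear almost everywhere), while area-based Bray–Curtis
β̄ rises (differentiation in how much area each type occupies):

```r
ts <- betaTimeseries(cl, w, "jaccard")
subset(ts, component == "total" & window_midpoint == 1950)$net_change
#> [1] -0.0076993
```

`runAlpha()` and `runBeta()` wrap these stages into config-driven runs that
write long-format CSV tables carrying the seed and a config hash.

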