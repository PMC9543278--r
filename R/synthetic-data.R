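# Seeded synthetic LUH2-like scenario generator.

# Temporal block start years: centuries before the anthropogenic onset year,
# decades from the onset to the end of the span. Values are held constant
# within blocks, emulating the coarser pre-1700 resolution of harmonized
# land-use reconstructions.
.blockStarts <- function(yearStart, yearEnd, onset) {
  pre <- if (onset > yearStart) {
    seq(yearStart, min(onset - 1L, yearEnd), by = 100L)
  } else integer(0)
  post <- if (onset <= yearEnd) {
    seq(max(onset, yearStart), yearEnd, by = 10L)
  } else integer(0)
  sort(unique(c(pre, post)))
}

#' Generate a synthetic land-use history in the LUH2 schema
#'
#' Simulates yearly maps of the 12 LUH2 "states" fraction layers on a
#' 0.25-degree lon-lat grid. Each cell starts as a seeded mix of primary and
#' secondary vegetation plus a small agricultural share (pasture and annual
#' crops); anthropogenic area then expands by converting primary vegetation in
#' proportion to its remaining stock (secondary vegetation is drawn down only
#' once primary cover falls below 5% of the land), at `0.1 * expansionRate`
#' per year before `anthroOnsetYear` and `expansionRate` after. Newly
#' converted area is allocated across the eight anthropogenic layers with
#' cell-specific weights; each layer activates only once the cell's cumulative
#' converted share passes a seeded threshold, so new ecosystem types appear
#' gradually. Values are piecewise constant within centuries before the onset
#' and within decades after it. With `noiseSd > 0`, logit-scale observation
#' noise is applied to each block's positive fractions and renormalized so
#' closure (fractions summing to the land fraction) is exact; zero fractions
#' stay zero, so noise never alters presence patterns. In the noise-free
#' setting every anthropogenic layer is non-decreasing in time.
#'
#' @param params A [ScenarioParams-class] object.
#' @return A [LandUseGrid-class] with the 12 LUH2 type labels; identical
#'   `params` (including `seed`) give bit-identical output.
#' @seealso [generateZoneMaps()], [writeLUH2States()]
#' @export
generateHistory <- function(params) {
  if (!is(params, "ScenarioParams")) {
    .err("ecodivParameterError", "'params' must be a ScenarioParams object")
  }
  validObject(params)
  set.seed(params@seed)
  nLon <- params@nLon
  nLat <- params@nLat
  n <- nLon * nLat
  lonEdges <- params@lonOrigin + 0.25 * (0:nLon)
  latEdges <- params@latOrigin + 0.25 * (0:nLat)

  landFrac <- params@landFractionMap
  if (!length(landFrac)) {
    u <- stats::runif(n)
    partial <- stats::runif(n, 0.05, 0.95)
    landFrac <- ifelse(u < 0.06, 0, ifelse(u < 0.18, partial, 1))
  }

  # Initial shares of land (rows sum to 1): four natural layers plus a small
  # year-start agricultural share split between pasture and annual C3 crops.
  natShape <- c(primf = 4, primn = 2, secdf = 1.2, secdn = 1.2)
  g <- matrix(stats::rgamma(n * 4L, shape = rep(natShape, each = n)), n, 4L)
  secMask <- matrix(stats::runif(n * 2L) < 0.7, n, 2L)
  g[, 3:4] <- g[, 3:4] * secMask
  a0 <- stats::runif(n, 0, 0.08)
  wInit <- matrix(stats::runif(n * 2L), n, 2L)
  wInit <- wInit / rowSums(wInit)

  # Anthropogenic layers in LUH2 order of appearance below:
  # pastr, range, urban, c3ann, c3per, c4ann, c4per, c3nfx.
  anthroNames <- c("pastr", "range", "urban", "c3ann", "c3per", "c4ann",
                   "c4per", "c3nfx")
  wAnthro <- matrix(stats::rgamma(n * 8L, shape = 0.8) + 1e-9, n, 8L)
  theta <- matrix(stats::runif(n * 8L, 0, 0.55), n, 8L)
  theta[, c(1L, 4L)] <- 0  # pasture and annual crops active from the start

  natural <- g / rowSums(g) * (1 - a0)
  anthro <- matrix(0, n, 8L)
  anthro[, 1L] <- a0 * wInit[, 1L]
  anthro[, 4L] <- a0 * wInit[, 2L]
  converted <- a0

  years <- params@yearStart:params@yearEnd
  nYears <- length(years)
  starts <- .blockStarts(params@yearStart, params@yearEnd, params@anthroOnsetYear)
  typeNames <- .LUH2_TYPES
  fractions <- lapply(typeNames, function(t) matrix(0, n, nYears))
  names(fractions) <- typeNames
  natCols <- c("primf", "primn", "secdf", "secdn")

  storeBlock <- function(shares12, cols) {
    for (j in seq_along(typeNames)) {
      fractions[[j]][, cols] <<- shares12[, j] * landFrac
    }
  }

  for (i in seq_along(starts)) {
    if (i > 1L) {
      dt <- starts[i] - starts[i - 1L]
      r <- params@expansionRate *
        if (starts[i - 1L] < params@anthroOnsetYear) 0.1 else 1
      fConv <- 1 - exp(-r * dt)
      pTot <- natural[, 1L] + natural[, 2L]
      dP <- pTot * fConv
      shareP <- ifelse(pTot > 0, 1, 0)
      # secondary is converted only where primary cover is nearly gone
      sTot <- natural[, 3L] + natural[, 4L]
      useSec <- pTot < 0.05
      dS <- ifelse(useSec, sTot * fConv, 0)
      # remove pro-rata within primary / secondary stocks
      fracP <- ifelse(pTot > 0, dP / pTot, 0)
      natural[, 1:2] <- natural[, 1:2] * (1 - fracP)
      fracS <- ifelse(sTot > 0, dS / sTot, 0)
      natural[, 3:4] <- natural[, 3:4] * (1 - fracS)
      inc <- dP * shareP + dS
      converted <- converted + inc
      active <- theta <= converted
      wAct <- wAnthro * active
      wAct <- wAct / rowSums(wAct)
      anthro <- anthro + inc * wAct
    }
    shares <- cbind(natural, anthro)
    colnames(shares) <- c(natCols, anthroNames)
    rs <- rowSums(shares)
    shares <- shares / ifelse(rs > 0, rs, 1)
    if (params@noiseSd > 0) {
      eps <- matrix(stats::rnorm(n * 12L, 0, params@noiseSd), n, 12L)
      pos <- shares > 0
      s <- pmin(pmax(shares, 1e-12), 1 - 1e-12)
      noisy <- stats::plogis(stats::qlogis(s) + eps)
      noisy[!pos] <- 0
      rsn <- rowSums(noisy)
      shares <- noisy / ifelse(rsn > 0, rsn, 1)
    }
    blockEnd <- if (i < length(starts)) starts[i + 1L] - 1L else params@yearEnd
    cols <- which(years >= starts[i] & years <= blockEnd)
    storeBlock(shares[, typeNames], cols)
  }

  LandUseGrid(
    fractions = fractions, years = years,
    xEdges = .projX(lonEdges), yEdges = .projY(latEdges),
    landArea = NULL, gridType = "lonlat",
    lonEdges = lonEdges, latEdges = latEdges
  )
}

#' Generate synthetic biome and region zone maps
#'
#' Biomes are contiguous longitudinal bands and regions contiguous latitudinal
#' bands on the scenario's 0.25-degree grid; every zone is non-empty when the
#' grid has at least as many columns (rows) as biomes (regions). The layout is
#' deterministic given the parameters.
#'
#' @param params A [ScenarioParams-class] object.
#' @return A [ZoneMaps-class] object on the scenario grid.
#' @export
generateZoneMaps <- function(params) {
  if (!is(params, "ScenarioParams")) {
    .err("ecodivParameterError", "'params' must be a ScenarioParams object")
  }
  validObject(params)
  nLon <- params@nLon
  nLat <- params@nLat
  ix <- rep(seq_len(nLon), times = nLat)
  iy <- rep(seq_len(nLat), each = nLon)
  biome <- ceiling(ix * params@nBiomes / nLon)
  region <- ceiling(iy * params@nRegions / nLat)
  lonEdges <- params@lonOrigin + 0.25 * (0:nLon)
  latEdges <- params@latOrigin + 0.25 * (0:nLat)
  ZoneMaps(biome, region, .projX(lonEdges), .projY(latEdges))
}

#' Zone maps as a long table
#'
#' @param zones A [ZoneMaps-class] object.
#' @return `data.frame` with `cell_id` (0-based, row-major from the
#'   south-west), `biome_id`, `region_id`.
#' @export
zoneMapsToDataFrame <- function(zones) {
  stopifnot(is(zones, "ZoneMaps"))
  data.frame(
    cell_id = seq_along(zones@biome) - 1L,
    biome_id = zones@biome,
    region_id = zones@region
  )
}
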