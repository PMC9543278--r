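# Classification of the 12 LUH2 land-use layers into ecosystem types.

# Base nine ecosystem types: four (semi-)natural plus five anthropogenic.
# Annual crop layers (c3ann, c4ann, c3nfx) group to cropland and perennial
# (woody) crop layers (c3per, c4per) to tree plantations.
.BASE9 <- c(
  "primary_forested", "primary_nonforested",
  "secondary_forested", "secondary_nonforested",
  "pasture", "rangeland", "urban", "cropland", "tree_plantation"
)
.NATURAL_BASE <- .BASE9[1:4]
.ANTHRO_BASE <- .BASE9[5:9]
.LUH2_TO_BASE9 <- c(
  primf = "primary_forested", primn = "primary_nonforested",
  secdf = "secondary_forested", secdn = "secondary_nonforested",
  pastr = "pasture", range = "rangeland", urban = "urban",
  c3ann = "cropland", c4ann = "cropland", c3nfx = "cropland",
  c3per = "tree_plantation", c4per = "tree_plantation"
)

#' Built-in ecosystem classification schemes
#'
#' Constructs one of the three classification schemes mapping (LUH2 land-use
#' layer, biome) to an ecosystem type id:
#' * `base9` — 9 biome-independent types (ids `<type>@GLOBAL`);
#' * `natural_x_biome` — the 4 natural types are distinct per biome
#'   (`<type>@<biome>`), the 5 anthropogenic types are global, giving
#'   `4 * nBiomes + 5` types (61 with 14 biomes);
#' * `all_x_biome` — all 9 types distinct per biome, giving `9 * nBiomes`
#'   types (126 with 14 biomes).
#'
#' @param name Scheme name.
#' @param nBiomes Number of biomes (ignored for `base9`).
#' @return A [ClassificationScheme-class].
#' @export
classificationScheme <- function(name = c("base9", "natural_x_biome", "all_x_biome"),
                                 nBiomes = 14L) {
  name <- match.arg(name)
  nBiomes <- as.integer(nBiomes)
  if (nBiomes < 1L) .err("ecodivParameterError", "nBiomes must be >= 1")
  lu <- names(.LUH2_TO_BASE9)
  base <- unname(.LUH2_TO_BASE9)
  crossed <- switch(name,
    base9 = character(0),
    natural_x_biome = .NATURAL_BASE,
    all_x_biome = .BASE9
  )
  rows <- lapply(seq_along(lu), function(i) {
    if (base[i] %in% crossed) {
      data.frame(landUse = lu[i], biome = seq_len(nBiomes),
                 ecosystemType = sprintf("%s@%d", base[i], seq_len(nBiomes)))
    } else {
      data.frame(landUse = lu[i], biome = NA_integer_,
                 ecosystemType = sprintf("%s@GLOBAL", base[i]))
    }
  })
  mapping <- do.call(rbind, rows)
  labels <- unique(unlist(lapply(.BASE9, function(b) {
    if (b %in% crossed) sprintf("%s@%d", b, seq_len(nBiomes))
    else sprintf("%s@GLOBAL", b)
  })))
  new("ClassificationScheme", schemeName = name, nBiomes = nBiomes,
      mapping = mapping, typeLabels = labels)
}

#' Number of ecosystem types under a scheme
#'
#' @param name Scheme name (`base9`, `natural_x_biome`, `all_x_biome`).
#' @param nBiomes Number of biomes.
#' @return Integer type count: 9; `4 * nBiomes + 5`; or `9 * nBiomes`.
#' @examples
#' schemeTypeCount("natural_x_biome", 14) # 61
#' schemeTypeCount("all_x_biome", 14)     # 126
#' @export
schemeTypeCount <- function(name, nBiomes = 14L) {
  if (length(name) != 1L ||
      !name %in% c("base9", "natural_x_biome", "all_x_biome")) {
    .err("ecodivParameterError", "unknown scheme '%s'", paste(name, collapse = ","))
  }
  nBiomes <- as.integer(nBiomes)
  if (nBiomes < 1L) .err("ecodivParameterError", "nBiomes must be >= 1")
  switch(name,
    base9 = 9L,
    natural_x_biome = 4L * nBiomes + 5L,
    all_x_biome = 9L * nBiomes
  )
}

#' Apply a classification scheme to a 12-layer grid
#'
#' Re-labels the 12 LUH2 fraction layers as ecosystem types by summing the
#' member layers per mapping row; for biome-crossed types a layer's fraction
#' contributes only in cells assigned to that biome. Fraction mass (and hence
#' closure) is conserved per cell and year.
#'
#' @param grid A [LandUseGrid-class] with the 12 LUH2 labels. For schemes
#'   other than `base9` the grid must carry `biomeId` in its `rowData` (see
#'   [overlayZones()]).
#' @param scheme A [ClassificationScheme-class].
#' @return A [LandUseGrid-class] whose assays are the scheme's ecosystem
#'   types.
#' @export
applyScheme <- function(grid, scheme) {
  stopifnot(is(grid, "LandUseGrid"), is(scheme, "ClassificationScheme"))
  if (!identical(sort(typeLabels(grid)), sort(.LUH2_TYPES))) {
    .err("ecodivParameterError", "grid must carry the 12 LUH2 land-use labels")
  }
  m <- scheme@mapping
  needsBiome <- any(!is.na(m$biome))
  rd <- rowData(grid)
  if (needsBiome) {
    if (!"biomeId" %in% colnames(rd)) {
      .err("ecodivParameterError",
           "scheme '%s' needs biome assignments; run overlayZones() first",
           scheme@schemeName)
    }
    land <- rd$landArea > 0
    unmapped <- setdiff(unique(rd$biomeId[land]), seq_len(scheme@nBiomes))
    if (length(unmapped)) {
      .err("ecodivMappingError",
           "biome id(s) %s not covered by scheme '%s'",
           paste(unmapped, collapse = ", "), scheme@schemeName)
    }
  }
  n <- nrow(grid)
  nYears <- ncol(grid)
  out <- lapply(scheme@typeLabels, function(t) matrix(0, n, nYears))
  names(out) <- scheme@typeLabels
  for (i in seq_len(nrow(m))) {
    a <- assay(grid, m$landUse[i])
    t <- m$ecosystemType[i]
    if (is.na(m$biome[i])) {
      out[[t]] <- out[[t]] + a
    } else {
      rows <- which(rd$biomeId == m$biome[i])
      if (length(rows)) {
        out[[t]][rows, ] <- out[[t]][rows, ] + a[rows, , drop = FALSE]
      }
    }
  }
  md <- metadata(grid)
  res <- LandUseGrid(
    fractions = out, years = gridYears(grid),
    xEdges = md$xEdges, yEdges = md$yEdges,
    landArea = landArea(grid), gridType = md$gridType,
    lonEdges = md$lonEdges, latEdges = md$latEdges
  )
  # carry zone assignments through
  rdo <- rowData(res)
  for (col in intersect(c("biomeId", "regionId", "isBoundary"), colnames(rd))) {
    rdo[[col]] <- rd[[col]]
  }
  rowData(res) <- rdo
  res
}
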