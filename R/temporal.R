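# Window averaging, baselining, weighted spatial means, stratified bootstrap
# and the presence-persistence statistic.

#' Build contiguous time windows
#'
#' Cuts the span `[startYear, endYear]` into contiguous non-overlapping
#' windows of `width` years. A trailing partial window is dropped with a
#' message. The representative midpoint is `start + width / 2`, so the
#' 900-999 century maps to 950 and the 1700-1709 decade to 1705.
#'
#' @param startYear,endYear Span in calendar years CE (inclusive).
#' @param width Window width in years (e.g. 100 or 10).
#' @return `data.frame` with columns `start`, `end`, `midpoint`.
#' @examples
#' nrow(makeWindows(900, 2000, 100))  # 11 centurial windows
#' nrow(makeWindows(1700, 2000, 10))  # 30 decadal windows
#' @export
makeWindows <- function(startYear, endYear, width) {
  .assertScalarNumber(width, "width")
  if (width < 1) .err("ecodivParameterError", "width must be >= 1 year")
  span <- endYear - startYear + 1
  k <- span %/% width
  if (k < 1) {
    .err("ecodivParameterError",
         "span %d-%d holds no full window of %d years", startYear, endYear, width)
  }
  if (span %% width != 0) {
    message(sprintf("makeWindows: trailing partial window of %d year(s) dropped",
                    span %% width))
  }
  start <- startYear + (seq_len(k) - 1) * width
  data.frame(start = start, end = start + width - 1, midpoint = start + width / 2)
}

#' Within-window means of yearly values
#'
#' Averages yearly per-cell values within each window. `NA` years (e.g.
#' Pielou evenness in single-type cells) are excluded from the mean; a window
#' whose years are all `NA` is `NA`.
#'
#' @param values Cells x years numeric matrix (or a vector for one cell).
#' @param years Calendar year of each column.
#' @param windows Window table from [makeWindows()].
#' @return Cells x windows matrix with midpoints as column names.
#' @export
windowMean <- function(values, years, windows) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (ncol(values) != length(years)) {
    .err("ecodivParameterError", "ncol(values) must equal length(years)")
  }
  out <- matrix(NA_real_, nrow(values), nrow(windows),
                dimnames = list(rownames(values), windows$midpoint))
  for (w in seq_len(nrow(windows))) {
    cols <- which(years >= windows$start[w] & years <= windows$end[w])
    if (!length(cols)) next
    mw <- rowMeans(values[, cols, drop = FALSE], na.rm = TRUE)
    mw[is.nan(mw)] <- NA_real_
    out[, w] <- mw
  }
  out
}

#' Net change relative to a baseline window
#'
#' Subtracts each cell's baseline-window value, so the baseline column is 0.
#' Cells with an undefined baseline become all-`NA` (excluded, with a
#' message).
#'
#' @param windowValues Cells x windows matrix (see [windowMean()]).
#' @param baseline Baseline window column index (default the first).
#' @return Matrix of the same shape.
#' @export
netChange <- function(windowValues, baseline = 1L) {
  base <- windowValues[, baseline]
  nUndef <- sum(is.na(base) & rowSums(!is.na(windowValues)) > 0)
  if (nUndef > 0) {
    message(sprintf("netChange: %d cell(s) with undefined baseline excluded", nUndef))
  }
  out <- windowValues - base
  out[is.na(base), ] <- NA_real_
  out
}

#' Land-area-weighted spatial means
#'
#' Weighted mean of cell values per window, globally or per group (e.g. IPBES
#' region or biome). Undefined cells are excluded from both numerator and
#' denominator; empty groups are skipped with a message.
#'
#' @param windowValues Cells x windows matrix.
#' @param weights Per-cell weights (land areas, km^2), positive.
#' @param groups Optional per-cell group labels; `NULL` for a single global
#'   group.
#' @return Groups x windows matrix.
#' @export
weightedSpatialMean <- function(windowValues, weights, groups = NULL) {
  if (length(weights) != nrow(windowValues)) {
    .err("ecodivParameterError", "one weight per cell required")
  }
  if (any(weights <= 0)) {
    .err("ecodivParameterError", "weights must be positive")
  }
  if (is.null(groups)) groups <- rep("global", nrow(windowValues))
  gl <- unique(groups)
  out <- matrix(NA_real_, length(gl), ncol(windowValues),
                dimnames = list(gl, colnames(windowValues)))
  for (g in seq_along(gl)) {
    rows <- which(groups == gl[g])
    if (!length(rows)) {
      message(sprintf("weightedSpatialMean: empty group '%s' skipped", gl[g]))
      next
    }
    v <- windowValues[rows, , drop = FALSE]
    w <- weights[rows]
    num <- colSums(v * w, na.rm = TRUE)
    den <- colSums((!is.na(v)) * w)
    out[g, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

# Largest-remainder allocation of nSample across strata, proportional to
# stratum sizes; every allocation is within 1 of exact proportionality.
.stratifiedAllocation <- function(strata, nSample) {
  sizes <- table(strata)
  exact <- nSample * as.numeric(sizes) / sum(sizes)
  alloc <- floor(exact)
  rem <- nSample - sum(alloc)
  if (rem > 0) {
    ord <- order(exact - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  names(alloc) <- names(sizes)
  if (any(alloc > as.numeric(sizes))) {
    .err("ecodivAllocationError",
         "stratum smaller than its allocation: %s",
         paste(names(sizes)[alloc > as.numeric(sizes)], collapse = ", "))
  }
  alloc
}

#' Stratified bootstrap of weighted spatial means
#'
#' Draws `nDraws` random samples of `nSample` cells without replacement, with
#' per-stratum counts proportional to stratum sizes (largest-remainder
#' rounding, so counts sum exactly to `nSample`), computes the land-area
#' weighted spatial mean per window for each draw, and summarizes the draw
#' means by their 1st and 9th deciles (the interdecile band, where 80% of the
#' draw means fall).
#'
#' @param windowValues Cells x windows matrix of per-cell values.
#' @param weights Per-cell land areas (km^2).
#' @param strata Per-cell stratum labels (e.g. region ids).
#' @param nSample Cells per draw (must not exceed the number of cells).
#' @param nDraws Number of draws.
#' @param seed Optional RNG seed.
#' @return List with `drawMeans` (draws x windows), `decile1`, `decile9`
#'   (per-window bounds), `allocation` (cells per stratum) and `nSample`.
#' @export
bootstrapMeans <- function(windowValues, weights, strata, nSample,
                           nDraws = 1000L, seed = NULL) {
  n <- nrow(windowValues)
  if (length(weights) != n || length(strata) != n) {
    .err("ecodivParameterError", "weights and strata must match the cell count")
  }
  nSample <- as.integer(nSample)
  if (nSample < 1L || nSample > n) {
    .err("ecodivParameterError", "nSample must be in [1, number of cells]")
  }
  alloc <- .stratifiedAllocation(strata, nSample)
  if (!is.null(seed)) set.seed(seed)
  strataIdx <- split(seq_len(n), strata)
  nW <- ncol(windowValues)
  drawMeans <- matrix(NA_real_, nDraws, nW,
                      dimnames = list(NULL, colnames(windowValues)))
  for (dr in seq_len(nDraws)) {
    idx <- unlist(lapply(names(alloc), function(s) {
      .resample(strataIdx[[s]], alloc[[s]])
    }), use.names = FALSE)
    v <- windowValues[idx, , drop = FALSE]
    w <- weights[idx]
    num <- colSums(v * w, na.rm = TRUE)
    den <- colSums((!is.na(v)) * w)
    drawMeans[dr, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  dec <- apply(drawMeans, 2L, .interdecile)
  list(
    drawMeans = drawMeans,
    decile1 = dec[1L, ],
    decile9 = dec[2L, ],
    allocation = alloc,
    nSample = nSample
  )
}

#' Non-overlap significance rule for interdecile bands
#'
#' A change between two time windows is judged significant when their
#' bootstrap interdecile bands do not overlap.
#'
#' @param intervalA,intervalB Length-2 numeric vectors `(decile1, decile9)`.
#' @return `TRUE` iff the intervals are disjoint.
#' @export
significantChange <- function(intervalA, intervalB) {
  if (length(intervalA) != 2L || length(intervalB) != 2L) {
    .err("ecodivParameterError", "intervals must have length 2")
  }
  a <- sort(intervalA)
  b <- sort(intervalB)
  a[2L] < b[1L] || b[2L] < a[1L]
}

#' Presence persistence of an ecosystem type between two windows
#'
#' Among retained cells where the type is present in at least one year of
#' window A, the fraction that also have presence in at least one year of
#' window B.
#'
#' @param grid A classified [LandUseGrid-class].
#' @param type Type label (one of `typeLabels(grid)`).
#' @param windowA,windowB Length-2 year ranges `c(start, end)` or single rows
#'   of a [makeWindows()] table.
#' @param presenceThreshold Minimum area (km^2) counting as presence.
#' @return Fraction in `[0, 1]`, or `NA_real_` when the type is present
#'   nowhere in window A.
#' @export
presencePersistence <- function(grid, type, windowA, windowB,
                                presenceThreshold = 0) {
  stopifnot(is(grid, "LandUseGrid"))
  if (!type %in% typeLabels(grid)) {
    .err("ecodivParameterError", "unknown type '%s'", type)
  }
  rng <- function(w) {
    if (is.data.frame(w)) c(w$start[1L], w$end[1L]) else as.numeric(w[1:2])
  }
  years <- gridYears(grid)
  presentIn <- function(w) {
    cols <- which(years >= rng(w)[1L] & years <= rng(w)[2L])
    if (!length(cols)) {
      .err("ecodivParameterError", "window outside the grid span")
    }
    a <- assay(grid, type)[, cols, drop = FALSE] * cellArea(grid)
    rowSums(a > presenceThreshold) > 0
  }
  keep <- retainedCells(grid)
  inA <- presentIn(windowA) & keep
  if (!any(inA)) {
    message("presencePersistence: type absent everywhere in window A")
    return(NA_real_)
  }
  inB <- presentIn(windowB)
  mean(inB[inA])
}
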