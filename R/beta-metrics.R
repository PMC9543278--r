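# Pairwise beta-diversity indices with Baselga-family decompositions, and the
# mean pairwise dissimilarity estimator across grain and extent.

#' Jaccard dissimilarity with turnover/nestedness decomposition
#'
#' For two presence vectors with `a` shared and `b`, `c` unique types:
#' `beta_jac = (b + c) / (a + b + c)`,
#' `beta_jtu = 2 min(b, c) / (a + 2 min(b, c))` (turnover) and
#' `beta_jne = beta_jac - beta_jtu` (nestedness-resultant). The components sum
#' exactly to the total.
#'
#' @param presenceA,presenceB Logical or 0/1 vectors over the same type set,
#'   each with at least one present type.
#' @return Named numeric vector `c(beta_jac, beta_jtu, beta_jne)`.
#' @export
jaccardDecomposition <- function(presenceA, presenceB) {
  pa <- as.logical(presenceA)
  pb <- as.logical(presenceB)
  if (length(pa) != length(pb)) {
    .err("ecodivParameterError", "presence vectors must have equal length")
  }
  if (!any(pa) || !any(pb)) {
    .err("ecodivUndefinedPair", "undefined pair: a cell has no types present")
  }
  a <- sum(pa & pb)
  b <- sum(pa & !pb)
  cc <- sum(!pa & pb)
  jac <- (b + cc) / (a + b + cc)
  m <- min(b, cc)
  jtu <- if (a + 2 * m == 0) 0 else 2 * m / (a + 2 * m)
  c(beta_jac = jac, beta_jtu = jtu, beta_jne = jac - jtu)
}

#' Bray-Curtis dissimilarity with balanced/gradient decomposition
#'
#' For two non-negative abundance (area) vectors with
#' `A = sum(min(x, y))`, `B = sum(x) - A`, `C = sum(y) - A`:
#' `beta_bc = (B + C) / (2A + B + C)`,
#' `beta_bc_bal = min(B, C) / (A + min(B, C))` (balanced variation: some types
#' gain area while others lose) and `beta_bc_gra = beta_bc - beta_bc_bal`
#' (abundance gradient: uniform gain or loss). The components sum exactly to
#' the total.
#'
#' @param areaA,areaB Non-negative vectors over the same type set, each with a
#'   positive total.
#' @return Named numeric vector `c(beta_bc, beta_bc_bal, beta_bc_gra)`.
#' @export
brayCurtisDecomposition <- function(areaA, areaB) {
  x <- as.numeric(areaA)
  y <- as.numeric(areaB)
  if (length(x) != length(y)) {
    .err("ecodivParameterError", "area vectors must have equal length")
  }
  if (any(x < 0) || any(y < 0)) {
    .err("ecodivParameterError", "areas must be non-negative")
  }
  if (sum(x) <= 0 || sum(y) <= 0) {
    .err("ecodivUndefinedPair", "undefined pair: a cell has zero total area")
  }
  A <- sum(pmin(x, y))
  B <- sum(x) - A
  C <- sum(y) - A
  bc <- (B + C) / (2 * A + B + C)
  m <- min(B, C)
  bal <- if (A + m == 0) 1 else m / (A + m)
  if (A + m == 0 && m == 0) bal <- 0 # unreachable for valid input; guard
  c(beta_bc = bc, beta_bc_bal = bal, beta_bc_gra = bc - bal)
}

# Vectorized pair computations. X is cells x types (presence logical for
# jaccard, areas for braycurtis); ia/ib index the pairs.
.pairsJaccard <- function(X, ia, ib) {
  Xa <- X[ia, , drop = FALSE]
  Xb <- X[ib, , drop = FALSE]
  a <- rowSums(Xa & Xb)
  b <- rowSums(Xa & !Xb)
  cc <- rowSums(!Xa & Xb)
  jac <- (b + cc) / (a + b + cc)
  m <- pmin(b, cc)
  jtu <- ifelse(a + 2 * m == 0, 0, 2 * m / (a + 2 * m))
  cbind(total = jac, component1 = jtu, component2 = jac - jtu)
}

.pairsBrayCurtis <- function(X, ia, ib) {
  Xa <- X[ia, , drop = FALSE]
  Xb <- X[ib, , drop = FALSE]
  A <- rowSums(pmin(Xa, Xb))
  B <- rowSums(Xa) - A
  C <- rowSums(Xb) - A
  bc <- (B + C) / (2 * A + B + C)
  m <- pmin(B, C)
  bal <- ifelse(A + m == 0, 1, m / (A + m))
  cbind(total = bc, component1 = bal, component2 = bc - bal)
}

.betaComponents <- function(index) {
  switch(index,
    jaccard = c("beta_jac", "beta_jtu", "beta_jne"),
    braycurtis = c("beta_bc", "beta_bc_bal", "beta_bc_gra")
  )
}

# All unordered pairs among cell indices `cells`, optionally restricted to
# pairs sharing an extent window (block of extentFactor x extentFactor grid
# cells). Returns list(ia, ib); windows with < 2 cells contribute no pairs.
.pairUniverse <- function(grid, cells, extentFactor = NULL) {
  if (is.null(extentFactor)) {
    if (length(cells) < 2L) {
      .err("ecodivParameterError", "fewer than two retained cells")
    }
    idx <- utils::combn(length(cells), 2L)
    return(list(ia = cells[idx[1L, ]], ib = cells[idx[2L, ]]))
  }
  e <- as.integer(extentFactor)
  if (e < 2L) .err("ecodivParameterError", "extent factor must be >= 2")
  rd <- rowData(grid)
  bx <- (rd$ix[cells] - 1L) %/% e
  by <- (rd$iy[cells] - 1L) %/% e
  win <- bx + by * (max(bx) + 1L)
  ia <- integer(0)
  ib <- integer(0)
  skipped <- 0L
  for (w in unique(win)) {
    cw <- cells[win == w]
    if (length(cw) < 2L) {
      skipped <- skipped + 1L
      next
    }
    idx <- utils::combn(length(cw), 2L)
    ia <- c(ia, cw[idx[1L, ]])
    ib <- c(ib, cw[idx[2L, ]])
  }
  if (skipped > 0L) {
    message(sprintf("%d extent window(s) with fewer than 2 cells skipped", skipped))
  }
  if (!length(ia)) {
    .err("ecodivParameterError", "no extent window holds two or more cells")
  }
  list(ia = ia, ib = ib)
}

# Mean over pairs of the within-window temporal mean dissimilarity, for one
# set of pairs and one set of year indices. Returns c(total, comp1, comp2).
.pairWindowMean <- function(grid, pairs, yearIdx, index, presenceThreshold) {
  groups <- .distinctYearGroups(grid, yearIdx)
  acc <- 0
  for (gi in seq_along(groups$rep)) {
    X <- .areaAt(grid, groups$rep[gi])
    vals <- if (index == "jaccard") {
      .pairsJaccard(X > presenceThreshold, pairs$ia, pairs$ib)
    } else {
      .pairsBrayCurtis(X, pairs$ia, pairs$ib)
    }
    acc <- acc + colMeans(vals) * groups$weight[gi]
  }
  acc / sum(groups$weight)
}

#' Mean pairwise dissimilarity at a grain and extent
#'
#' Estimates the average pairwise dissimilarity `beta_bar = sum(p_ki) / N`
#' between pairs of retained grid cells, for one time window: each pair's
#' dissimilarity is first averaged over the window's years, then averaged over
#' pairs. At sub-global extent only pairs lying in the same extent window
#' (block of `extentFactor` x `extentFactor` cells) qualify; at global extent
#' (`extentFactor = NULL`) all pairs qualify. With `nDraws > 1` the pair
#' universe is subsampled: each draw samples `sampleSize` cells uniformly
#' without replacement, `beta_bar` is computed per draw, and the 1st/9th
#' deciles over draws are reported.
#'
#' @param grid A classified [LandUseGrid-class] at the analysis grain (see
#'   [aggregateGrain()]).
#' @param index `"jaccard"` (incidence) or `"braycurtis"` (area-based).
#' @param years Calendar years of the time window (default: all years).
#' @param extentFactor Extent window size in grid cells, or `NULL` for global.
#' @param nDraws Number of random draws (1 = exhaustive pair universe).
#' @param sampleSize Cells per draw (required when `nDraws > 1`).
#' @param seed RNG seed for the draws.
#' @param presenceThreshold Minimum area (km^2) counting as presence.
#' @return `data.frame` with one row per component (`total` plus the two
#'   decomposition components), columns `index`, `component`, `beta_bar`,
#'   `n_pairs`, `n_draws`, `decile_1`, `decile_9`; per-draw means are attached
#'   as attribute `"draw_means"`.
#' @export
meanPairwiseDissimilarity <- function(grid, index = c("jaccard", "braycurtis"),
                                      years = NULL, extentFactor = NULL,
                                      nDraws = 1L, sampleSize = NULL,
                                      seed = NULL, presenceThreshold = 0) {
  stopifnot(is(grid, "LandUseGrid"))
  index <- match.arg(index)
  if (is.null(years)) years <- gridYears(grid)
  yearIdx <- match(years, gridYears(grid))
  if (anyNA(yearIdx)) .err("ecodivParameterError", "years outside the grid span")
  cells <- which(retainedCells(grid))
  comps <- .betaComponents(index)
  nDraws <- as.integer(nDraws)
  if (nDraws < 1L) .err("ecodivParameterError", "nDraws must be >= 1")

  if (nDraws == 1L && is.null(sampleSize)) {
    pairs <- .pairUniverse(grid, cells, extentFactor)
    bb <- .pairWindowMean(grid, pairs, yearIdx, index, presenceThreshold)
    res <- data.frame(
      index = index, component = c("total", comps[2:3]),
      beta_bar = as.numeric(bb), n_pairs = length(pairs$ia),
      n_draws = 1L, decile_1 = NA_real_, decile_9 = NA_real_
    )
    attr(res, "draw_means") <- matrix(bb, nrow = 1,
                                      dimnames = list(NULL, names(bb)))
    return(res)
  }
  if (is.null(sampleSize)) {
    .err("ecodivParameterError", "sampleSize is required when nDraws > 1")
  }
  sampleSize <- as.integer(sampleSize)
  if (sampleSize < 2L || sampleSize > length(cells)) {
    .err("ecodivParameterError",
         "sampleSize must be in [2, number of retained cells]")
  }
  if (!is.null(seed)) set.seed(seed)
  drawMeans <- matrix(NA_real_, nDraws, 3L)
  nPairs <- integer(nDraws)
  for (dr in seq_len(nDraws)) {
    cs <- .resample(cells, sampleSize)
    pairs <- .pairUniverse(grid, cs, extentFactor)
    drawMeans[dr, ] <- .pairWindowMean(grid, pairs, yearIdx, index,
                                       presenceThreshold)
    nPairs[dr] <- length(pairs$ia)
  }
  dec <- apply(drawMeans, 2L, .interdecile)
  res <- data.frame(
    index = index, component = c("total", comps[2:3]),
    beta_bar = colMeans(drawMeans), n_pairs = as.integer(round(mean(nPairs))),
    n_draws = nDraws, decile_1 = dec[1L, ], decile_9 = dec[2L, ]
  )
  attr(res, "draw_means") <- drawMeans
  res
}

#' Time series of mean pairwise dissimilarity with net change
#'
#' Computes `beta_bar` per time window at a fixed grain and extent, and its
#' net change relative to the first (baseline) window. When subsampling, the
#' same cell draws are reused across windows so each draw traces a coherent
#' trajectory; reported deciles are over the draws' values (absolute and net
#' change).
#'
#' @inheritParams meanPairwiseDissimilarity
#' @param windows Window table from [makeWindows()].
#' @return `data.frame` with columns `window_midpoint`, `index`, `component`,
#'   `beta_bar`, `net_change`, `decile_1`, `decile_9`, `nc_decile_1`,
#'   `nc_decile_9`, `n_pairs`, `n_draws`.
#' @export
betaTimeseries <- function(grid, windows, index = c("jaccard", "braycurtis"),
                           extentFactor = NULL, nDraws = 1L, sampleSize = NULL,
                           seed = NULL, presenceThreshold = 0) {
  stopifnot(is(grid, "LandUseGrid"))
  index <- match.arg(index)
  years <- gridYears(grid)
  comps <- .betaComponents(index)
  nDraws <- as.integer(nDraws)
  cells <- which(retainedCells(grid))

  # fix the pair universes up front: one exhaustive universe, or one cell
  # sample (hence pair set) per draw, shared by every window
  if (nDraws == 1L && is.null(sampleSize)) {
    pairSets <- list(.pairUniverse(grid, cells, extentFactor))
  } else {
    if (is.null(sampleSize)) {
      .err("ecodivParameterError", "sampleSize is required when nDraws > 1")
    }
    sampleSize <- as.integer(sampleSize)
    if (sampleSize < 2L || sampleSize > length(cells)) {
      .err("ecodivParameterError",
           "sampleSize must be in [2, number of retained cells]")
    }
    if (!is.null(seed)) set.seed(seed)
    pairSets <- lapply(seq_len(nDraws), function(dr) {
      .pairUniverse(grid, .resample(cells, sampleSize), extentFactor)
    })
  }

  nW <- nrow(windows)
  perDraw <- array(NA_real_, c(length(pairSets), nW, 3L))
  for (w in seq_len(nW)) {
    yearIdx <- which(years >= windows$start[w] & years <= windows$end[w])
    if (!length(yearIdx)) {
      .err("ecodivParameterError", "window %d lies outside the grid span", w)
    }
    for (dr in seq_along(pairSets)) {
      perDraw[dr, w, ] <- .pairWindowMean(grid, pairSets[[dr]], yearIdx,
                                          index, presenceThreshold)
    }
  }
  baseline <- matrix(perDraw[, 1L, ], ncol = 3L)
  out <- do.call(rbind, lapply(seq_len(nW), function(w) {
    m <- matrix(perDraw[, w, ], ncol = 3L)
    nm <- m - baseline
    data.frame(
      window_midpoint = windows$midpoint[w],
      index = index,
      component = c("total", comps[2:3]),
      beta_bar = colMeans(m),
      net_change = colMeans(nm),
      decile_1 = apply(m, 2L, function(v) .interdecile(v)[1L]),
      decile_9 = apply(m, 2L, function(v) .interdecile(v)[2L]),
      nc_decile_1 = apply(nm, 2L, function(v) .interdecile(v)[1L]),
      nc_decile_9 = apply(nm, 2L, function(v) .interdecile(v)[2L]),
      n_pairs = as.integer(round(mean(vapply(pairSets,
                                             function(p) length(p$ia), 1)))),
      n_draws = length(pairSets)
    )
  }))
  rownames(out) <- NULL
  out
}
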