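# Per-cell alpha-diversity metrics on compositions of ecosystem coverage.

# Validate a composition vector: non-negative, at least one positive entry.
# If requireUnit, positive entries must sum to 1 within 1e-6.
.checkComposition <- function(p, requireUnit = TRUE) {
  if (!is.numeric(p) || length(p) == 0L || any(!is.finite(p)) || any(p < 0)) {
    .err("ecodivParameterError", "composition must be non-negative and finite")
  }
  if (all(p == 0)) {
    .err("ecodivUndefinedComposition", "empty composition: no type present")
  }
  if (requireUnit && abs(sum(p) - 1) > 1e-6) {
    .err("ecodivParameterError",
         "composition proportions must sum to 1 (got %.8f)", sum(p))
  }
  invisible(p)
}

#' Ecosystem richness of a composition
#'
#' Number of ecosystem types with strictly positive proportional area.
#'
#' @param p Numeric vector of proportional areas (zeros allowed for absent
#'   types).
#' @return Integer count of present types.
#' @export
richness <- function(p) {
  .checkComposition(p, requireUnit = FALSE)
  sum(p > 0)
}

#' Shannon diversity of a composition
#'
#' `H' = -sum(p_i * log(p_i))` over present types, in nats. Zero iff a single
#' type is present; at most `log(E)` with equality iff the composition is
#' uniform over its `E` present types.
#'
#' @inheritParams richness
#' @return Shannon index (nats).
#' @export
shannonIndex <- function(p) {
  .checkComposition(p)
  pp <- p[p > 0]
  -sum(pp * log(pp))
}

#' Pielou evenness of a composition
#'
#' `J = H' / log(E)`, defined only for compositions with two or more present
#' types; `NA` otherwise (undefined cells are dropped, not zero-filled, in
#' spatial averages).
#'
#' @inheritParams richness
#' @return Evenness in `(0, 1]`, or `NA_real_` when fewer than two types are
#'   present.
#' @export
pielouEvenness <- function(p) {
  .checkComposition(p)
  E <- sum(p > 0)
  if (E < 2L) return(NA_real_)
  shannonIndex(p) / log(E)
}

#' Gini-Simpson diversity of a composition
#'
#' `D = 1 - sum(p_i^2)`: the probability that two points dropped at random in
#' the cell's land fall in different ecosystem types. Zero iff one type is
#' present; at most `(E - 1) / E`, attained at the uniform composition.
#'
#' @inheritParams richness
#' @return Simpson index in `[0, 1)`.
#' @export
giniSimpson <- function(p) {
  .checkComposition(p)
  1 - sum(p^2)
}

#' Rao's quadratic entropy of a composition
#'
#' `RaoQ = sum_i sum_j d_ij p_i p_j` over ordered pairs of present types: the
#' expected compositional distance between two random points in the cell.
#' Equals the Gini-Simpson index when all off-diagonal `d_ij = 1`, and is
#' bounded by it in general.
#'
#' @inheritParams richness
#' @param d Symmetric dissimilarity matrix with zero diagonal. If `p` is
#'   named, `d` is aligned by name; otherwise `length(p)` must match
#'   `nrow(d)`.
#' @return Rao's Q in `[0, 1]`.
#' @export
raoQ <- function(p, d) {
  .checkComposition(p)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    .err("ecodivParameterError", "'d' must be a square matrix")
  }
  if (!is.null(names(p))) {
    if (!all(names(p) %in% rownames(d))) {
      .err("ecodivMappingError", "type(s) %s absent from the dissimilarity matrix",
           paste(setdiff(names(p), rownames(d)), collapse = ", "))
    }
    d <- d[names(p), names(p), drop = FALSE]
  } else if (length(p) != nrow(d)) {
    .err("ecodivMappingError",
         "composition length %d does not match matrix dimension %d",
         length(p), nrow(d))
  }
  as.numeric(t(p) %*% d %*% p)
}

#' All alpha-diversity metrics for every cell and year
#'
#' Computes richness, Shannon, Pielou, Gini-Simpson and (when a dissimilarity
#' matrix is given) Rao's Q from each cell's coverage composition — the
#' proportional land area of each ecosystem type, renormalized over present
#' types. Cells without land are `NA`; Pielou is `NA` where fewer than two
#' types are present.
#'
#' @param grid A classified [LandUseGrid-class].
#' @param dissimilarity Optional 9 x 9 base-type dissimilarity matrix (see
#'   [buildDissimilarityMatrix()]); requires the `base9` scheme's type ids.
#' @param presenceThreshold Minimum area (km^2) for a type to count as
#'   present.
#' @return Named list of cells x years matrices: `richness`, `shannon`,
#'   `pielou`, `simpson`, and `raoq` when `dissimilarity` is supplied.
#' @export
alphaDiversity <- function(grid, dissimilarity = NULL, presenceThreshold = 0) {
  stopifnot(is(grid, "LandUseGrid"))
  n <- nrow(grid)
  nYears <- ncol(grid)
  years <- gridYears(grid)
  dn <- list(NULL, as.character(years))
  mats <- list(
    richness = matrix(NA_real_, n, nYears, dimnames = dn),
    shannon = matrix(NA_real_, n, nYears, dimnames = dn),
    pielou = matrix(NA_real_, n, nYears, dimnames = dn),
    simpson = matrix(NA_real_, n, nYears, dimnames = dn)
  )
  Dm <- NULL
  if (!is.null(dissimilarity)) {
    Dm <- .alignDissimilarity(typeLabels(grid), dissimilarity)
    mats$raoq <- matrix(NA_real_, n, nYears, dimnames = dn)
  }
  la <- landArea(grid)
  hasLand <- la > 0
  # compute once per distinct yearly state and replicate across its run
  groups <- .distinctYearGroups(grid, seq_len(nYears))
  runEnd <- cumsum(groups$weight)
  runStart <- runEnd - groups$weight + 1L
  for (gi in seq_along(groups$rep)) {
    y <- groups$rep[gi]
    cols <- runStart[gi]:runEnd[gi]
    area <- .areaAt(grid, y)
    present <- area > presenceThreshold
    p <- area * present
    tot <- rowSums(p)
    p <- p / ifelse(tot > 0, tot, 1)
    rich <- rowSums(present)
    xlogx <- p * log(p)
    xlogx[p == 0] <- 0
    H <- -rowSums(xlogx)
    J <- ifelse(rich >= 2, H / log(pmax(rich, 2)), NA_real_)
    D <- 1 - rowSums(p^2)
    q <- if (!is.null(Dm)) rowSums((p %*% Dm) * p) else NULL
    for (cc in cols) {
      mats$richness[hasLand, cc] <- rich[hasLand]
      mats$shannon[hasLand, cc] <- H[hasLand]
      mats$pielou[hasLand, cc] <- J[hasLand]
      mats$simpson[hasLand, cc] <- D[hasLand]
      if (!is.null(q)) mats$raoq[hasLand, cc] <- q[hasLand]
    }
  }
  mats
}
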