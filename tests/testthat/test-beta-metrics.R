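test_that("Jaccard decomposition reproduces worked presence pairs", {
  expect_equal(jaccardDecomposition(c(1, 1, 0), c(1, 1, 0)),
               c(beta_jac = 0, beta_jtu = 0, beta_jne = 0))
  # {A,B} vs {B,C}: pure turnover
  expect_equal(jaccardDecomposition(c(1, 1, 0), c(0, 1, 1)),
               c(beta_jac = 2 / 3, beta_jtu = 2 / 3, beta_jne = 0))
  # {A,B} vs {A}: pure nestedness (a=1, b=1, c=0 -> (1/2, 0, 1/2))
  expect_equal(jaccardDecomposition(c(1, 1), c(1, 0)),
               c(beta_jac = 1 / 2, beta_jtu = 0, beta_jne = 1 / 2))
  # disjoint sets: total dissimilarity
  expect_equal(unname(jaccardDecomposition(c(1, 0), c(0, 1))[1]), 1)
  expect_error(jaccardDecomposition(c(0, 0), c(1, 0)),
               class = "ecodivUndefinedPair")
})

test_that("Bray-Curtis decomposition reproduces worked area pairs", {
  expect_equal(brayCurtisDecomposition(c(2, 1), c(2, 1)),
               c(beta_bc = 0, beta_bc_bal = 0, beta_bc_gra = 0))
  # x=(3,1), y=(1,1): pure abundance gradient
  expect_equal(brayCurtisDecomposition(c(3, 1), c(1, 1)),
               c(beta_bc = 1 / 3, beta_bc_bal = 0, beta_bc_gra = 1 / 3))
  # x=(2,0), y=(0,2): pure balanced turnover
  expect_equal(brayCurtisDecomposition(c(2, 0), c(0, 2)),
               c(beta_bc = 1, beta_bc_bal = 1, beta_bc_gra = 0))
  expect_error(brayCurtisDecomposition(c(0, 0), c(1, 0)),
               class = "ecodivUndefinedPair")
  expect_error(brayCurtisDecomposition(c(-1, 2), c(1, 0)),
               class = "ecodivParameterError")
})

test_that("decomposition identities, bounds and symmetry hold on random pairs", {
  set.seed(101)
  nTypes <- 6
  for (i in 1:400) {
    x <- round(runif(nTypes, 0, 5), 2)
    y <- round(runif(nTypes, 0, 5), 2)
    x[runif(nTypes) < 0.4] <- 0
    y[runif(nTypes) < 0.4] <- 0
    if (sum(x) == 0) x[1] <- 1
    if (sum(y) == 0) y[2] <- 1
    j <- jaccardDecomposition(x > 0, y > 0)
    b <- brayCurtisDecomposition(x, y)
    expect_lt(abs(j[1] - j[2] - j[3]), 1e-12)
    expect_lt(abs(b[1] - b[2] - b[3]), 1e-12)
    expect_true(all(j >= -1e-12 & j <= 1 + 1e-12))
    expect_true(all(b >= -1e-12 & b <= 1 + 1e-12))
    expect_equal(j, jaccardDecomposition(y > 0, x > 0)[c(1, 2, 3)])
    expect_equal(b, brayCurtisDecomposition(y, x)[c(1, 2, 3)])
    # presence-only index ignores a rescaling of one cell's areas, while the
    # Bray-Curtis gradient component generally reacts to it
    expect_equal(jaccardDecomposition((3 * x) > 0, y > 0), j)
    # beta_jac = 1 iff no shared types; beta_bc = 1 iff no shared area
    expect_equal(unname(j[1]) == 1, !any(x > 0 & y > 0))
    expect_equal(unname(b[1]) == 1, sum(pmin(x, y)) == 0)
  }
})

test_that("totals agree with vegan's Jaccard and Bray-Curtis distances", {
  skip_if_not_installed("vegan")
  set.seed(5)
  X <- matrix(rpois(10 * 6, 3), 10, 6)
  X[1, ] <- c(1, 0, 0, 0, 0, 2) # ensure non-degenerate rows
  vj <- as.matrix(vegan::vegdist(X > 0, method = "jaccard", binary = TRUE))
  vb <- as.matrix(vegan::vegdist(X, method = "bray"))
  for (a in 1:9) for (b in (a + 1):10) {
    expect_equal(unname(jaccardDecomposition(X[a, ] > 0, X[b, ] > 0)[1]),
                 vj[a, b], tolerance = 1e-12)
    expect_equal(unname(brayCurtisDecomposition(X[a, ], X[b, ])[1]),
                 vb[a, b], tolerance = 1e-12)
  }
})

test_that("mean pairwise dissimilarity equals the brute-force pair mean", {
  # 4 cells with known compositions -> mean over the 6 pairs
  fr <- list(
    A = matrix(c(0.6, 0.2, 0.0, 0.5), 4, 1),
    B = matrix(c(0.4, 0.8, 0.3, 0.0), 4, 1),
    C = matrix(c(0.0, 0.0, 0.7, 0.5), 4, 1)
  )
  g <- toyGrid(fr)
  res <- meanPairwiseDissimilarity(g, "braycurtis")
  X <- cbind(A = fr$A[, 1], B = fr$B[, 1], C = fr$C[, 1]) * cellArea(g)[1]
  pairs <- utils::combn(4, 2)
  brute <- rowMeans(apply(pairs, 2, function(pr) {
    brayCurtisDecomposition(X[pr[1], ], X[pr[2], ])
  }))
  expect_equal(res$beta_bar, unname(brute), tolerance = 1e-12)
  expect_equal(res$n_pairs, rep(6L, 3))
  resJ <- meanPairwiseDissimilarity(g, "jaccard")
  bruteJ <- rowMeans(apply(pairs, 2, function(pr) {
    jaccardDecomposition(X[pr[1], ] > 0, X[pr[2], ] > 0)
  }))
  expect_equal(resJ$beta_bar, unname(bruteJ), tolerance = 1e-12)
})

test_that("identical cells give zero dissimilarity at every grain and extent", {
  fr <- list(A = matrix(0.5, 8, 2), B = matrix(0.5, 8, 2))
  g <- toyGrid(fr)
  for (index in c("jaccard", "braycurtis")) {
    expect_equal(meanPairwiseDissimilarity(g, index)$beta_bar, rep(0, 3))
    expect_equal(meanPairwiseDissimilarity(g, index, extentFactor = 4)$beta_bar,
                 rep(0, 3))
  }
})

test_that("sub-global extents only compare cells within the same window", {
  # two 2-cell windows with contrasting compositions; cross-window pairs
  # would raise the within-window mean
  fr <- list(
    A = matrix(c(1, 1, 0, 0), 4, 1),
    B = matrix(c(0, 0, 1, 1), 4, 1)
  )
  g <- toyGrid(fr)
  res <- meanPairwiseDissimilarity(g, "jaccard", extentFactor = 2)
  expect_equal(res$beta_bar[1], 0)
  expect_equal(res$n_pairs[1], 2L)
  resG <- meanPairwiseDissimilarity(g, "jaccard")
  expect_gt(resG$beta_bar[1], 0)
})

test_that("subsampled beta_bar is consistent with the exhaustive pair mean", {
  p <- smallParams(nLon = 10, nLat = 6, noiseSd = 0.3, seed = 31,
                   yearStart = 1995, yearEnd = 2000,
                   landFractionMap = rep(1, 60))
  g <- generateHistory(p)
  full <- meanPairwiseDissimilarity(g, "braycurtis")
  sub <- meanPairwiseDissimilarity(g, "braycurtis", nDraws = 60,
                                   sampleSize = 20, seed = 99)
  dm <- attr(sub, "draw_means")
  se <- apply(dm, 2, stats::sd) / sqrt(nrow(dm))
  expect_true(all(abs(sub$beta_bar - full$beta_bar) <= 2 * se + 1e-12))
  expect_true(all(sub$decile_1 <= sub$beta_bar & sub$beta_bar <= sub$decile_9))
  # same seed, same draws
  sub2 <- meanPairwiseDissimilarity(g, "braycurtis", nDraws = 60,
                                    sampleSize = 20, seed = 99)
  expect_identical(sub$beta_bar, sub2$beta_bar)
})

test_that("beta time series capture homogenization and area divergence", {
  # static world: all net changes zero
  frS <- list(A = matrix(0.6, 6, 30), B = matrix(0.4, 6, 30))
  frS$A[2, ] <- 0.2; frS$B[2, ] <- 0.8
  gS <- toyGrid(frS, years = 1:30)
  w <- makeWindows(1, 30, 10)
  tsS <- betaTimeseries(gS, w, "braycurtis")
  expect_equal(tsS$net_change, rep(0, nrow(tsS)))

  # presences converge: a shared type spreads into every cell -> Jaccard
  # homogenization at the global extent
  n <- 6; Y <- 30
  unique_frac <- matrix(0, n, Y)
  shared <- matrix(rep(seq(0, 0.5, length.out = Y), each = n), n, Y)
  shared[, 1] <- 0
  uniq <- lapply(1:n, function(i) {
    m <- matrix(0, n, Y)
    m[i, ] <- 1 - shared[i, ]
    m
  })
  names(uniq) <- paste0("nat", 1:n)
  frC <- c(uniq, list(crop = shared))
  gC <- toyGrid(frC, years = 1:Y)
  tsC <- betaTimeseries(gC, w, "jaccard")
  last <- subset(tsC, component == "total" &
                   window_midpoint == max(window_midpoint))
  expect_lt(last$net_change, 0)

  # areas diverge while presences stay fixed: Bray-Curtis rises while
  # Jaccard is flat
  fx <- seq(0.5, 0.9, length.out = Y)
  frD <- list(
    X = rbind(fx, 1 - fx),
    Y = rbind(1 - fx, fx)
  )
  gD <- toyGrid(frD, years = 1:Y)
  tsD <- betaTimeseries(gD, w, "braycurtis")
  lastD <- subset(tsD, component == "total" &
                    window_midpoint == max(window_midpoint))
  expect_gt(lastD$net_change, 0)
  tsDj <- betaTimeseries(gD, w, "jaccard")
  expect_equal(tsDj$net_change, rep(0, nrow(tsDj)))
})
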