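test_that("scalar alpha metrics reproduce closed-form values", {
  expect_equal(richness(1.0), 1L)
  expect_equal(richness(c(0.5, 0.3, 0.2)), 3L)
  expect_equal(richness(c(0.5, 0, 0.5)), 2L)
  expect_error(richness(numeric(0)), class = "ecodivParameterError")
  expect_error(richness(c(0, 0)), class = "ecodivUndefinedComposition")

  expect_equal(shannonIndex(1.0), 0)
  expect_equal(shannonIndex(c(0.5, 0.5)), log(2))
  expect_equal(pielouEvenness(c(0.25, 0.25, 0.25, 0.25)), 1)
  expect_true(is.na(pielouEvenness(1.0)))
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(pielouEvenness(c(0.9, 0.1)), h / log(2))
  expect_equal(round(pielouEvenness(c(0.9, 0.1)), 4), 0.469)

  expect_equal(giniSimpson(1.0), 0)
  expect_equal(giniSimpson(c(0.5, 0.5)), 0.5)
  expect_equal(giniSimpson(c(0.5, 0.3, 0.2)), 1 - (0.25 + 0.09 + 0.04))
  expect_error(shannonIndex(c(0.2, 0.2)), class = "ecodivParameterError")
})

test_that("alpha metrics agree with vegan on random compositions", {
  skip_if_not_installed("vegan")
  set.seed(42)
  for (i in 1:25) {
    p <- randomComposition(sample(2:8, 1))
    expect_equal(shannonIndex(p), unname(vegan::diversity(p, "shannon")),
                 tolerance = 1e-12)
    expect_equal(giniSimpson(p), unname(vegan::diversity(p, "simpson")),
                 tolerance = 1e-12)
  }
})

test_that("Rao's Q evaluates the dissimilarity-weighted double sum", {
  d <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(raoQ(c(0.5, 0.5), d), 0.5)
  expect_equal(raoQ(c(1, 0), d), 0)
  d3 <- 1 - diag(3)
  expect_equal(raoQ(c(0.5, 0.3, 0.2), d3), 0.62)
  # brute-force double-sum oracle on random compositions and matrices
  set.seed(7)
  for (i in 1:20) {
    E <- sample(2:7, 1)
    p <- randomComposition(E)
    d <- matrix(runif(E^2), E, E)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    brute <- 0
    for (a in 1:E) for (b in 1:E) brute <- brute + d[a, b] * p[a] * p[b]
    expect_equal(raoQ(p, d), brute, tolerance = 1e-12)
    # invariant under relabeling
    perm <- sample(E)
    expect_equal(raoQ(p[perm], d[perm, perm]), raoQ(p, d), tolerance = 1e-12)
    # bounded by Gini-Simpson (d <= 1)
    expect_lte(raoQ(p, d), giniSimpson(p) + 1e-12)
  }
  expect_error(raoQ(c(a = 0.5, b = 0.5), d3), class = "ecodivMappingError")
})

test_that("merging two types with zero dissimilarity leaves Rao's Q unchanged", {
  set.seed(3)
  d <- matrix(runif(16, 0.2, 1), 4, 4)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0
  d[3:4, 2] <- d[2, 3:4] <- d[3:4, 1] # types 1 and 2 indistinguishable
  for (i in 1:10) {
    p <- randomComposition(4)
    merged <- c(p[1] + p[2], p[3], p[4])
    dm <- d[c(1, 3, 4), c(1, 3, 4)]
    expect_equal(raoQ(p, d), raoQ(merged, dm), tolerance = 1e-12)
  }
})

test_that("the dissimilarity builder applies the category mapping rules", {
  d <- defaultDissimilarityMatrix()
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 9))
  expect_equal(max(d), 1) # rescaled by the off-diagonal maximum
  # forested and non-forested primary share all values
  expect_equal(d["primary_forested", ], d["primary_nonforested", ],
               ignore_attr = TRUE)
  expect_equal(d["primary_forested", "primary_nonforested"], 0)
  expect_equal(d["pasture", "cropland"], d["rangeland", "cropland"])

  # averaging rule for non-forested secondary, on a toy source table
  src <- expand.grid(category_i = ecodivgrid:::.SOURCE_CATEGORIES,
                     category_j = ecodivgrid:::.SOURCE_CATEGORIES,
                     stringsAsFactors = FALSE)
  src <- src[src$category_i < src$category_j, ]
  src$d <- 1.0
  src$d[src$category_i == "cropland" &
          src$category_j == "intermediate secondary vegetation"] <- 0.4
  src$d[src$category_i == "cropland" &
          src$category_j == "young secondary vegetation"] <- 0.6
  dt <- buildDissimilarityMatrix(src)
  expect_equal(dt["secondary_nonforested", "cropland"], 0.5)

  expect_error(buildDissimilarityMatrix(src[src$category_i != "pasture" &
                                              src$category_j != "pasture", ]),
               class = "ecodivMappingError")
})

test_that("alphaDiversity matches the scalar metrics cell by cell", {
  p <- smallParams(noiseSd = 0.2, seed = 14, yearStart = 1995, yearEnd = 2000)
  g <- generateHistory(p)
  suppressMessages(g <- overlayZones(g, generateZoneMaps(p)))
  cl <- applyScheme(g, classificationScheme("base9", p@nBiomes))
  d <- defaultDissimilarityMatrix()
  a <- alphaDiversity(cl, d)
  keep <- which(retainedCells(cl))
  for (cell in keep[c(1, 5, 17)]) {
    st <- cellState(cl, cell, 2000)
    pvec <- st$coverage[st$coverage > 0]
    y <- which(gridYears(cl) == 2000)
    expect_equal(unname(a$richness[cell, y]), richness(pvec))
    expect_equal(unname(a$shannon[cell, y]), shannonIndex(pvec))
    expect_equal(unname(a$simpson[cell, y]), giniSimpson(pvec))
    expect_equal(unname(a$pielou[cell, y]), pielouEvenness(pvec))
    names(pvec) <- sub("@GLOBAL", "", names(pvec))
    expect_equal(unname(a$raoq[cell, y]), raoQ(pvec, d[names(pvec), names(pvec)]),
                 tolerance = 1e-12)
  }
})

test_that("a single-type world has degenerate alpha metrics everywhere", {
  side <- sqrt(769)
  n <- 6
  fr <- list(cropland = matrix(1, n, 2), other = matrix(0, n, 2))
  g <- LandUseGrid(fr, years = 1:2, xEdges = side * (0:n), yEdges = c(0, side),
                   gridType = "equalarea")
  a <- alphaDiversity(g)
  expect_true(all(a$richness == 1))
  expect_true(all(a$shannon == 0))
  expect_true(all(a$simpson == 0))
  expect_true(all(is.na(a$pielou)))
  # the all-zero extra layer changes nothing relative to a one-layer grid
  g1 <- LandUseGrid(fr["cropland"], years = 1:2, xEdges = side * (0:n),
                    yEdges = c(0, side), gridType = "equalarea")
  a1 <- alphaDiversity(g1)
  expect_equal(a$richness, a1$richness)
  expect_equal(a$shannon, a1$shannon)
})
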