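test_that("Jaccard distance counts bands, not double absences", {
  m <- rbind(g1 = c(1L, 1L, 0L, 0L),
             g2 = c(1L, 0L, 1L, 0L),
             g3 = c(1L, 1L, 0L, 0L),
             g4 = c(0L, 0L, 1L, 1L))
  d <- jaccardDistance(makePanel(m))
  expect_equal(d["g1", "g2"], 2 / 3)        # M11=1, M10=1, M01=1
  expect_equal(d["g1", "g3"], 0)            # identical profiles
  expect_equal(d["g1", "g4"], 1)            # disjoint band sets
  expect_true(isSymmetric(d))
})

test_that("Jaccard agrees with vegan on complete data and is metric", {
  skip_if_not_installed("vegan")
  p <- randomPanel(15, 40, seed = 21)
  d <- jaccardDistance(p)
  vd <- as.matrix(vegan::vegdist(markerCalls(p), method = "jaccard",
                                 binary = TRUE))
  expect_equal(unname(d), unname(vd), tolerance = 1e-12)
  # triangle inequality on complete-case data
  n <- nrow(d)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("pairs with no comparable informative markers are NA", {
  m <- rbind(g1 = c(1L, NA, 0L), g2 = c(NA, 1L, 0L), g3 = c(1L, 1L, 1L))
  expect_warning(d <- jaccardDistance(makePanel(m)), "comparable")
  expect_true(is.na(d["g1", "g2"]))   # only shared non-missing call is 0/0
  expect_false(is.na(d["g1", "g3"]))
})

test_that("PCoA reproduces classical-scaling geometry", {
  # three equidistant points: equilateral triangle, two equal eigenvalues
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  ord <- runPcoa(d, nAxes = 2)
  cd <- as.matrix(dist(ord$coordinates))
  off <- cd[upper.tri(cd)]
  expect_lt(max(off) - min(off), 1e-9)
  ev <- ord$eigenvalues[1:2]
  expect_lt(abs(ev[1] - ev[2]), 1e-9)

  # points on a line: first axis recovers the ordering
  x <- c(0, 1, 2, 5, 9)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("p", 1:5), paste0("p", 1:5))
  ord <- runPcoa(d, nAxes = 1)
  expect_true(all(diff(ord$coordinates[, 1]) > 0) ||
              all(diff(ord$coordinates[, 1]) < 0))

  # Euclidean distances: PCoA equals PCA scores up to sign
  set.seed(22)
  y <- matrix(rnorm(12 * 4), 12)
  d <- as.matrix(dist(y))
  ord <- runPcoa(d, nAxes = 3)
  pc <- prcomp(y)$x[, 1:3]
  for (j in 1:3)
    expect_true(max(abs(ord$coordinates[, j] - pc[, j])) < 1e-8 ||
                max(abs(ord$coordinates[, j] + pc[, j])) < 1e-8)
})

test_that("PCA matches a covariance eigendecomposition oracle", {
  p <- randomPanel(10, 20, seed = 23)
  ord <- runPca(p, nAxes = 5)
  x <- scale(markerCalls(p), center = TRUE, scale = FALSE)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(ord$explained, (ev / sum(ev))[1:5], tolerance = 1e-9)
  expect_lte(sum(ord$explained), 1 + 1e-12)
  expect_true(all(diff(ord$explained) <= 1e-12))
})

test_that("PCA separates structure and finds block loadings", {
  # two perfectly anticorrelated marker blocks: rank-1 structure
  set.seed(24)
  z <- rbinom(30, 1, 0.5)
  m <- cbind(matrix(z, 30, 5), matrix(1L - z, 30, 5))
  storage.mode(m) <- "integer"
  ord <- runPca(makePanel(m), nAxes = 3)
  expect_gt(ord$explained[1], 0.999)
  l1 <- ord$loadings[, 1]
  expect_true(all(sign(l1[1:5]) == sign(l1[1])) &&
              all(sign(l1[6:10]) == -sign(l1[1])))

  # simulated two-group panel: PC1 sign separates the groups
  cfg <- simConfig(groupSizes = c(12, 20), fst = 0.25, selectedBlock = NULL,
                   markersPerChromosome = c("1A" = 150), seed = 25)
  sp <- simulatePanel(cfg)
  sc <- runPca(sp)$coordinates[, 1]
  expect_gte(labelAgreement(sc > 0, genotypeGroups(sp)), 0.95)
})

test_that("top-loading selection returns the requested count, sign-blind", {
  p <- randomPanel(12, 100, seed = 26)
  ord <- runPca(p)
  top <- topLoadingMarkers(ord, fraction = 0.05, axis = 1)
  expect_identical(nrow(top), 5L)
  flip <- ord
  flip$loadings <- -ord$loadings
  expect_identical(topLoadingMarkers(flip, 0.05, 1)$marker, top$marker)
  expect_error(topLoadingMarkers(ord, fraction = 0), "fraction")
})

test_that("outlier flagging tolerates clusters but catches far points", {
  set.seed(27)
  coords <- matrix(rnorm(40 * 2), 40)
  coords[40, ] <- c(30, 30)   # ~10x the cloud spread
  rownames(coords) <- sprintf("g%02d", 1:40)
  ord <- structure(list(coordinates = coords, method = "PCA"),
                   class = "ordination")
  expect_identical(flagOutliers(ord), "g40")
  # sign flips do not change the flag set
  ord$coordinates <- -coords
  expect_identical(flagOutliers(ord), "g40")

  # homogeneous cloud at n = 92: flags are rare
  flags <- vapply(1:40, function(s) {
    set.seed(s)
    cc <- matrix(rnorm(92 * 2), 92)
    rownames(cc) <- sprintf("g%02d", 1:92)
    length(flagOutliers(structure(list(coordinates = cc), class = "ordination")))
  }, numeric(1))
  expect_gte(mean(flags == 0), 0.95)

  # a two-cluster panel is structure, not outliers
  cl <- rbind(matrix(rnorm(26 * 2, mean = 4, sd = 0.5), 26),
              matrix(rnorm(66 * 2, mean = 0, sd = 0.5), 66))
  rownames(cl) <- sprintf("g%02d", 1:92)
  expect_identical(
    flagOutliers(structure(list(coordinates = cl), class = "ordination")),
    character(0))
})

test_that("marker-group association flags confounded markers only", {
  # band perfectly confounded with a 26/66 split
  g <- rep(c("A", "B"), c(26, 66))
  m <- cbind(conf = as.integer(g == "A"),
             null = rep(c(0L, 1L), 46))
  p <- makePanel(m, groups = setNames(g, sprintf("g%02d", 1:92)))
  res <- markerGroupAssociation(p)
  expect_lt(res$p[res$marker == "conf"], 1e-15)
  expect_gt(res$p[res$marker == "null"], 0.05)
  expect_identical(res$effect[res$marker == "conf"], 1)

  # chi-square path agrees with a Fisher oracle within an order of
  # magnitude on a moderate table (20/6 carriers vs 10/56)
  m2 <- cbind(mod = c(rep(1L, 20), rep(0L, 6), rep(1L, 10), rep(0L, 56)),
              pad = rep(c(0L, 1L), 46))
  p2 <- makePanel(m2, groups = setNames(g, sprintf("g%02d", 1:92)))
  res2 <- markerGroupAssociation(p2)
  expect_identical(res2$test[res2$marker == "mod"], "chisq")
  pf <- fisher.test(matrix(c(20L, 6L, 10L, 56L), 2))$p.value
  expect_lt(abs(log10(res2$p[res2$marker == "mod"]) - log10(pf)), 1)

  expect_error(markerGroupAssociation(p, labels = setNames(
    rep(c("A", "B", "C"), length.out = 92), rownames(markerCalls(p)))),
    "two groups")
})
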