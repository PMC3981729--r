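test_that("duplicated marker columns give r2 = 1 at the minimum p", {
  x <- markerCalls(randomPanel(30, 1, seed = 41))
  m <- cbind(x, x)
  colnames(m) <- c("mA", "mB")
  pr <- pairR2(makePanel(m), map = lineMap(c("mA", "mB")), nPerm = 99,
               seed = 1)
  expect_equal(pr$r2, 1)
  expect_equal(pr$p, 1 / 100)
  expect_true(pr$significant)
})

test_that("r2 equals the haplotype-count formula on complete data", {
  set.seed(42)
  p <- randomPanel(40, 20, seed = 42)
  pr <- pairR2(p, map = lineMap(colnames(markerCalls(p))), nPerm = 0)
  x <- markerCalls(p)
  for (t in sample(nrow(pr), 50)) {
    a <- x[, pr$markerA[t]]; b <- x[, pr$markerB[t]]
    pA <- mean(a); pB <- mean(b)
    D <- mean(a * b) - pA * pB
    expect_equal(pr$r2[t], D^2 / (pA * (1 - pA) * pB * (1 - pB)),
                 tolerance = 1e-12)
  }
})

test_that("pair bookkeeping: distances, strictly-greater unlinked rule, skips", {
  m <- markerCalls(randomPanel(20, 4, seed = 43))
  m[, 4] <- 1L                      # monomorphic column
  map <- data.frame(marker = colnames(m), chrom = "5B",
                    pos = c(0, 50, 120, 10))
  pr <- pairR2(makePanel(m), map = map, nPerm = 19, seed = 2)
  expect_identical(attr(pr, "skipped"), 3L)   # monomorphic partner pairs
  d <- pr$dist[pr$markerA == "m001" & pr$markerB == "m002"]
  expect_identical(d, 50)
  expect_false(pr$unlinked[pr$dist == 50])    # exactly 50 cM is linked
  expect_true(all(pr$unlinked[pr$dist > 50]))
})

test_that("independent markers have null-scale r2", {
  p <- randomPanel(92, 150, seed = 44)
  pr <- pairR2(p, map = lineMap(colnames(markerCalls(p))), nPerm = 0)
  expect_gt(nrow(pr), 10000)
  expect_lt(abs(mean(pr$r2) - 1 / 91), 0.003)
})

test_that("the background is the interpolated 95th percentile of unlinked r2", {
  fake <- function(r2) data.frame(markerA = "a", markerB = "b", chrom = "1A",
                                  dist = 60, r2 = r2, p = 0.5, n = 90,
                                  significant = FALSE, unlinked = TRUE)
  expect_equal(backgroundLd(fake(rep(0.05, 30))), 0.05)
  expect_equal(backgroundLd(fake(seq(0.01, 1, by = 0.01))), 0.9505)
  # linked pairs cannot move the background
  pairs <- fake(seq(0.01, 1, by = 0.01))
  linked <- data.frame(markerA = "c", markerB = "d", chrom = "1A", dist = 5,
                       r2 = 1, p = 0.001, n = 90, significant = TRUE,
                       unlinked = FALSE)
  expect_equal(backgroundLd(rbind(pairs, linked)), 0.9505)
  expect_error(backgroundLd(fake(rep(0.1, 5))), "unlinked")
})

test_that("loess decay finds a constructed crossing and its absence", {
  mkPairs <- function(r2, d) data.frame(markerA = "a", markerB = "b",
                                        chrom = "1A", dist = d, r2 = r2,
                                        p = 0.01, n = 90, significant = TRUE,
                                        unlinked = d > 50)
  for (s in 1:5) {
    set.seed(s)
    d <- runif(400, 0, 40)
    r2 <- pmax(0, 0.6 - 0.02 * d) + rnorm(400, 0, 0.01)
    dec <- fitDecay(mkPairs(r2, d), background = 0.2)
    expect_false(dec$noIntercept)
    expect_lt(abs(dec$decayCM - 20), 2)
  }
  # curve everywhere above background: no intercept, extent reported
  set.seed(6)
  d <- runif(100, 0, 35)
  dec <- fitDecay(mkPairs(0.5 + rnorm(100, 0, 0.01), d), background = 0.2)
  expect_true(dec$noIntercept)
  expect_true(is.na(dec$decayCM))
  expect_equal(dec$maxExtent, max(dec$curve$dist))

  # raising the background can only shorten the decay distance
  set.seed(7)
  d <- runif(300, 0, 40)
  r2 <- pmax(0.05, 0.6 - 0.02 * d) + rnorm(300, 0, 0.01)
  d1 <- fitDecay(mkPairs(r2, d), background = 0.15)$decayCM
  d2 <- fitDecay(mkPairs(r2, d), background = 0.3)$decayCM
  expect_gte(d1, d2)

  expect_error(fitDecay(mkPairs(rep(0.5, 40), rep(3, 40)), 0.2), "degenerate")
  expect_error(fitDecay(mkPairs(0.5, 10)[0, ], 0.2), "significant")
})

test_that("stratified summaries are internally consistent", {
  cfg <- simConfig(groupSizes = 40, selectedBlock = NULL,
                   markersPerChromosome = c("1A" = 25, "3B" = 25, "2D" = 25),
                   chromosomeLengths = c("1A" = 100, "3B" = 100, "2D" = 100),
                   missingRate = 0.02, seed = 45)
  p <- simulateLdBlock(cfg, blockR2 = 0.1, dRef = 30)
  pr <- pairR2(p, nPerm = 49, seed = 3)
  s <- ldSummaries(pr, markerMap(p))

  # counts close: pairs split exactly into significant and not
  expect_identical(sum(s$perChromosome$nPairs), nrow(pr))
  expect_identical(sum(s$perChromosome$nSignificant), sum(pr$significant))

  # genome means are pair-count-weighted averages of chromosome means
  pc <- s$perChromosome
  for (g in unique(s$perGenome$genome)) {
    sel <- substring(pc$chrom, 2, 2) == g
    expect_equal(s$perGenome$meanR2[s$perGenome$genome == g],
                 weighted.mean(pc$meanR2[sel], pc$nPairs[sel]))
  }
  expect_equal(s$wholeGenome$meanR2, mean(pr$r2))

  # selection effect: significant-pair mean dominates the overall mean
  expect_gte(s$wholeGenome$meanR2Significant, s$wholeGenome$meanR2)

  # adjacent profile sits at the proximal locus of each successive pair
  map <- markerMap(p)
  adj <- s$adjacentProfile
  for (ch in unique(adj$chrom)) {
    mm <- map[map$chrom == ch, ]
    mm <- mm[order(mm$pos), ]
    sub <- adj[adj$chrom == ch, ]
    expect_identical(sub$markerA, mm$marker[-nrow(mm)])
    expect_equal(sub$pos, mm$pos[-nrow(mm)])
  }

  # three equally correlated markers: chromosome mean equals the common r2
  one <- data.frame(markerA = c("a", "a", "b"), markerB = c("b", "c", "c"),
                    chrom = "7D", dist = c(1, 2, 1), r2 = 0.4, p = 0.01,
                    n = 40, significant = TRUE, unlinked = FALSE)
  s1 <- ldSummaries(one, data.frame(marker = c("a", "b", "c"), chrom = "7D",
                                    pos = 1:3))
  expect_equal(s1$perChromosome$meanR2, 0.4)
})
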