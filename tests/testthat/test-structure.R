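test_that("K = 1 degenerates to a single-population fit", {
  p <- randomPanel(8, 20, seed = 1)
  fit <- runAdmixture(p, K = 1, burnin = 100, iters = 200, seed = 1)
  expect_true(all(membership(fit) == 1))
  expect_equal(lnEvidence(fit),
               mean(fit@loglik) - var(fit@loglik) / 2)
})

test_that("argument errors are caught", {
  p <- randomPanel(5, 10, seed = 2)
  expect_error(runAdmixture(p, K = 6, burnin = 10, iters = 10), "exceeds")
  expect_error(runAdmixture(p, K = 0, burnin = 10, iters = 10), "K")
  expect_error(runAdmixture(p, K = 2, burnin = 0, iters = 10), "positive")
})

test_that("membership rows sum to one and duplicates get equal memberships", {
  cfg <- simConfig(groupSizes = c(8, 8), fst = 0.3, selectedBlock = NULL,
                   markersPerChromosome = c("1A" = 60), missingRate = 0,
                   seed = 3)
  p <- simulatePanel(cfg)
  x <- markerCalls(p)
  dup <- rbind(x, dup1 = x[1, ], dup2 = x[1, ])
  rownames(dup) <- c(rownames(x), "dup1", "dup2")
  fit <- runAdmixture(makePanel(dup), K = 2, burnin = 1000, iters = 1000,
                      seed = 3)
  q <- membership(fit)
  expect_true(all(abs(rowSums(q) - 1) < 1e-9))
  expect_lt(max(abs(q["dup1", ] - q["dup2", ])), 0.05)
  expect_lt(max(abs(q["dup1", ] - q[rownames(x)[1], ])), 0.05)
})

test_that("two simulated groups are recovered at K = 2", {
  agree <- vapply(1:3, function(s) {
    cfg <- simConfig(groupSizes = c(10, 14), fst = 0.2, selectedBlock = NULL,
                     markersPerChromosome = c("1A" = 80, "2B" = 80),
                     missingRate = 0.02, seed = s)
    p <- simulatePanel(cfg)
    fit <- runAdmixture(p, K = 2, burnin = 1000, iters = 1000, seed = s)
    g <- assignGroups(membership(fit))
    labelAgreement(g$group, genotypeGroups(p))
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})

test_that("Evanno delta-K reproduces hand computations", {
  # linear L(K): zero second difference everywhere
  fits <- unlist(lapply(1:4, function(K)
    lapply(c(-1, 0, 1), function(d) fitStub(K, -1000 + 10 * K + d))),
    recursive = FALSE)
  ev <- selectKEvanno(fits)
  expect_equal(ev$table$deltaK[2:3], c(0, 0), tolerance = 1e-12)

  # the worked 5-point example: deltaK(2) = |10 - 400| / 5 = 78
  L <- c(-1000, -600, -590, -585, -582)
  fits <- unlist(lapply(1:5, function(K)
    lapply(c(-5, 0, 5), function(d) fitStub(K, L[K] + d))),
    recursive = FALSE)
  ev <- selectKEvanno(fits)
  expect_equal(ev$table$sdLnE, rep(5, 5))
  expect_equal(ev$table$deltaK[2], 78)
  expect_identical(ev$bestK, 2L)

  # zero replicate spread: deltaK undefined, excluded from the argmax
  fits <- unlist(lapply(1:4, function(K) {
    reps <- if (K == 2) c(0, 0, 0) else c(-1, 0, 1)
    lapply(reps, function(d) fitStub(K, L[K] + d))
  }), recursive = FALSE)
  ev <- selectKEvanno(fits)
  expect_true(is.na(ev$table$deltaK[ev$table$K == 2]))
  expect_identical(ev$bestK, 3L)
})

test_that("group assignment follows argmax with the tie and admixture rules", {
  q <- rbind(a = c(0.9, 0.1), b = c(0.5, 0.5), c = c(0.25, 0.75))
  g <- assignGroups(q)
  expect_identical(g$group, c("G1", "G1", "G2"))
  expect_identical(g$admixed, c(FALSE, TRUE, FALSE))

  # invariant under column permutation up to relabelling (tie-free rows:
  # an exact tie resolves to the lowest index under either ordering)
  q2 <- q[c("a", "c"), ]
  expect_identical(assignGroups(q2)$group == "G1",
                   assignGroups(q2[, 2:1])$group == "G2")
})

test_that("aligning replicate runs undoes label switching", {
  set.seed(9)
  q <- t(apply(matrix(rexp(30 * 3), 30), 1, function(v) v / sum(v)))
  rownames(q) <- sprintf("g%02d", 1:30)
  colnames(q) <- paste0("K", 1:3)
  perm <- c(3, 1, 2)
  expect_equal(alignQ(q[, perm], q), q)
})

test_that("LD pruning keeps one marker per duplicated cluster", {
  p <- randomPanel(40, 12, seed = 10)
  kept <- pruneByLd(p, map = lineMap(colnames(markerCalls(p))),
                    nPerm = 199, seed = 1)
  # independent markers mostly retained (each candidate faces one 5%
  # false-positive test per already-retained marker, so a few drop)
  expect_gte(length(kept), 8)

  x <- markerCalls(randomPanel(40, 4, seed = 11))
  dup <- cbind(x, x, x)[, c(1, 5, 9, 2, 6, 10, 3, 7, 11, 4, 8, 12)]
  colnames(dup) <- sprintf("m%03d", 1:12)
  kept <- pruneByLd(makePanel(dup), map = lineMap(colnames(dup)),
                    nPerm = 199, seed = 1)
  expect_identical(kept, c("m001", "m004", "m007", "m010"))
})

test_that("pruning equals a step-by-step greedy oracle", {
  # same greedy contract, written independently: scan in map order,
  # test against every retained marker, drop on first significance
  p <- randomPanel(30, 30, missing = 0.05, seed = 12)
  map <- data.frame(marker = colnames(markerCalls(p)),
                    chrom = rep(c("1A", "2B", "3D"), each = 10),
                    pos = rep(1:10, 3))
  kept <- pruneByLd(p, map = map, alpha = 0.05, nPerm = 99, seed = 21)

  x <- markerCalls(p)
  set.seed(21)
  oracle <- character(0)
  for (ch in unique(map$chrom)) {
    ids <- map$marker[map$chrom == ch][order(map$pos[map$chrom == ch])]
    ret <- character(0)
    for (id in ids) {
      sig <- FALSE
      for (r in ret) {
        pv <- dartpop:::.pair_r2_perm(x, match(r, colnames(x)),
                                      match(id, colnames(x)), 99L)$p[1]
        if (!is.na(pv) && pv < 0.05) { sig <- TRUE; break }
      }
      if (!sig) ret <- c(ret, id)
    }
    oracle <- c(oracle, ret)
  }
  expect_identical(kept, oracle)
})
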