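test_that("NJ start tree recovers the generating topology on clean data", {
  set.seed(31)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.1, 0.3))
  aln <- simulateAlignment(tr, gtrModel(shape = NA, nCat = 1L), 3000,
                           seed = 1)
  expect_equal(bipartitionDistance(buildStartTree(aln), tr), 0)
  # 3 taxa: unique unrooted topology
  a3 <- partitionedAlignment(c(a = "ACGT", b = "ACGA", c = "AGGA"), "nt")
  t3 <- buildStartTree(a3)
  expect_equal(length(t3$tip.label), 3L)
  # identical sequences: clamped near-zero branch lengths
  a0 <- partitionedAlignment(c(a = "ACGT", b = "ACGT", c = "ACGT",
                               d = "ACGT"), "nt")
  expect_true(all(buildStartTree(a0)$edge.length <= 1e-5))
})

test_that("two-taxon JC branch-length MLE matches the closed form", {
  # 100 sites, 10 mismatches: t-hat = -3/4 log(1 - 4p/3)
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
  aln <- partitionedAlignment(c(a = s1, b = s2), "nt")
  tr <- parseNewick("(a:0.05,b:0.05);")
  fit <- optimizeBranchLengths(tr, aln, gtrModel(shape = NA, nCat = 1L),
                               tol = 1e-9)
  that <- sum(fit@edgeLengths[[1]])
  expect_equal(that, -3 / 4 * log(1 - 4 * 0.1 / 3), tolerance = 1e-6)
})

test_that("branch-length optimization never decreases the likelihood", {
  set.seed(41)
  for (i in 1:3) {
    inst <- randomInstance(6, 60)
    tr <- inst$tree
    tr$edge.length <- rep(0.3, nrow(tr$edge))
    before <- sum(siteLogLik(ape::unroot(tr), inst$aln, inst$model))
    fit <- optimizeBranchLengths(tr, inst$aln, inst$model, tol = 1e-4)
    expect_gte(fit@logLik, before)
  }
})

test_that("data simulated at zero distance drives lengths to the bound", {
  aln <- partitionedAlignment(c(a = paste(rep("ACGT", 25), collapse = ""),
                                b = paste(rep("ACGT", 25), collapse = "")),
                              "nt")
  fit <- optimizeBranchLengths(parseNewick("(a:0.1,b:0.1);"), aln,
                               gtrModel(shape = NA, nCat = 1L), tol = 1e-8)
  expect_lt(sum(fit@edgeLengths[[1]]), 1e-6)
})

test_that("NNI neighborhoods have size 2(n-3) and differ by one split", {
  set.seed(13)
  for (n in c(4, 7, 10)) {
    phy <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 0.3)))
    nb <- nniNeighbors(phy)
    expect_length(nb, 2 * (n - 3))
    for (t2 in nb) {
      expect_equal(bipartitionDistance(phy, t2), 2)  # one split swapped out
      expect_equal(sort(t2$edge.length), sort(phy$edge.length))
    }
    # no duplicate neighbors
    keys <- vapply(nb, function(t2)
      paste(sort(rootgraft:::.bipartitionKeys(t2)), collapse = ";"),
      character(1))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("four-taxon search equals exhaustive topology comparison", {
  set.seed(59)
  tr <- parseNewick("((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);")
  m <- gtrModel(shape = 1)
  aln <- simulateAlignment(tr, m, 800, seed = 3)
  fit <- mlSearch(aln, m, searchConfig(tol = 1e-4))
  tops <- c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  lnls <- vapply(tops, function(s) {
    t0 <- parseNewick(s)
    t0$edge.length <- rep(0.1, nrow(t0$edge))
    optimizeBranchLengths(t0, aln, m, tol = 1e-4)@logLik
  }, numeric(1))
  expect_equal(fit@logLik, max(lnls), tolerance = 1e-2)
  best <- parseNewick(tops[which.max(lnls)])
  expect_equal(bipartitionDistance(fit@tree, best), 0)
  expect_gte(fit@logLik,
             optimizeBranchLengths(buildStartTree(aln), aln, m,
                                   tol = 1e-4)@logLik - 1e-6)
})

test_that("gamma shape and GTR rates are recovered from simulated data", {
  set.seed(77)
  tr <- ape::rtree(10, br = function(n) runif(n, 0.08, 0.35))
  gen <- gtrModel(rates = c(1, 1, 1, 1, 1, 1), shape = 1, nCat = 4L)
  aln <- simulateAlignment(tr, gen, 4000, seed = 9)
  fit <- optimizeBranchLengths(tr, aln, gtrModel(shape = 0.3), tol = 1e-3)
  fit <- optimizeModelParameters(fit, aln, tol = 1e-3)
  alpha <- fit@models[[1]]@gammaShape
  expect_gt(alpha, 0.7)
  expect_lt(alpha, 1.45)
  rates <- rootgraft:::.gtrRateVector(fit@models[[1]])
  expect_true(all(rates / rates[6] > 0.6 & rates / rates[6] < 1.6))
  # single-category model ignores the shape entirely
  m1 <- gtrModel(shape = NA, nCat = 1L)
  f1 <- optimizeBranchLengths(tr, aln, m1, tol = 1e-3)
  f2 <- optimizeModelParameters(f1, aln, tol = 1e-3)
  expect_true(is.na(f2@models[[1]]@gammaShape))
})

test_that("constrained search honours monophyly and nested hypotheses", {
  set.seed(83)
  tr <- ape::rtree(7, br = function(n) runif(n, 0.1, 0.3))
  m <- gtrModel(shape = NA, nCat = 1L)
  aln <- simulateAlignment(tr, m, 500, seed = 2)
  free <- mlSearch(aln, m, searchConfig(tol = 1e-3))
  # a group far apart in the free ML tree
  labs <- free@tree$tip.label
  far <- rootgraft:::.edgeTipSets(free@tree)
  grp <- c(labs[1], setdiff(labs, unlist(far[which(
    vapply(far, function(s) labs[1] %in% s, logical(1)))[1]]))[1])
  grp <- unique(grp)
  if (length(grp) < 2) grp <- labs[1:2]
  con <- constrainedMlSearch(aln, m, list(grp), searchConfig(tol = 1e-3))
  expect_true(isMonophyletic(con@tree, grp))
  expect_lte(con@logLik, free@logLik + 1e-6)
  # constraining an already-monophyletic clade changes nothing
  keys <- rootgraft:::.bipartitionKeys(free@tree)
  sets <- rootgraft:::.edgeTipSets(free@tree)
  inner <- sets[[as.integer(names(keys)[1])]]
  con2 <- constrainedMlSearch(aln, m, list(inner), searchConfig(tol = 1e-3))
  expect_equal(con2@logLik, free@logLik, tolerance = 0.05)
  expect_error(constrainedMlSearch(aln, m,
                                   list(labs[1:3], labs[2:5]),
                                   searchConfig()),
               "overlap")
})

test_that("search is reproducible for a fixed configuration", {
  set.seed(99)
  inst <- randomInstance(7, 300)
  f1 <- mlSearch(inst$aln, inst$model, searchConfig(tol = 1e-2, seed = 4))
  f2 <- mlSearch(inst$aln, inst$model, searchConfig(tol = 1e-2, seed = 4))
  expect_identical(writeNewick(f1@tree), writeNewick(f2@tree))
  expect_identical(f1@logLik, f2@logLik)
})
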