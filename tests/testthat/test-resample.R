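test_that("bootstrap replicates preserve partition widths and seeding", {
  set.seed(1)
  m <- matrix(sample(c("A", "C", "G", "T"), 3 * 30, TRUE), 3,
              dimnames = list(c("a", "b", "c"), NULL))
  aln <- partitionedAlignment(m, partitions = data.frame(
    name = c("p1", "p2", "p3"), alphabet = "nt",
    start = c(0L, 12L, 20L), end = c(12L, 20L, 30L), model = "GTR+G4"))
  reps <- bootstrapResample(aln, B = 5, seed = 7)
  for (r in reps) {
    p <- partitionScheme(r)
    expect_equal(p$end - p$start, c(12L, 8L, 10L))
  }
  i1 <- bootstrapResample(aln, B = 3, seed = 9, indicesOnly = TRUE)
  i2 <- bootstrapResample(aln, B = 3, seed = 9, indicesOnly = TRUE)
  expect_identical(i1, i2)
  # indices never cross partition boundaries
  pidx <- rootgraft:::.partitionIndex(aln)
  for (ii in i1) expect_identical(pidx[ii], pidx)
  # width-1 partition resamples to itself
  a1 <- partitionedAlignment(m[, 1, drop = FALSE])
  expect_identical(alignmentMatrix(bootstrapResample(a1, 1, seed = 1)[[1]]),
                   m[, 1, drop = FALSE])
})

test_that("bootstrap supports count bipartitions correctly", {
  set.seed(5)
  ref <- ape::unroot(ape::rtree(8))
  sup <- bootstrapSupport(rep(list(ref), 10), ref)
  labs <- sup$node.label[nzchar(sup$node.label)]
  expect_true(all(labs == "100"))
  # half-and-half replicate set gives 50 on the disputed branch
  nb <- nniNeighbors(ref)[[1]]
  sup2 <- bootstrapSupport(c(rep(list(ref), 5), rep(list(nb), 5)), ref)
  vals <- as.numeric(sup2$node.label[nzchar(sup2$node.label)])
  expect_true(50 %in% vals)
  # agreement with an independent counting oracle on random trees
  trees <- lapply(1:25, function(i) ape::rtree(7))
  ref7 <- ape::rtree(7)
  mine <- bootstrapSupport(trees, ref7)
  keys <- rootgraft:::.bipartitionKeys(ref7)
  oracle <- naiveSupportCounts(trees, ref7)
  n <- length(ref7$tip.label)
  for (j in seq_along(keys)) {
    e <- as.integer(names(keys)[j])
    lab <- mine$node.label[ref7$edge[e, 2] - n]
    if (keys[j] %in% names(oracle))
      expect_equal(as.numeric(lab), 100 * oracle[[keys[j]]] / 25)
  }
  expect_error(bootstrapSupport(list(ape::rtree(6)), ref7), "mismatch")
})

test_that("RELL replicate means converge to observed totals", {
  set.seed(3)
  V <- matrix(rnorm(3 * 80, mean = -2), 3, 80,
              dimnames = list(c("t1", "t2", "t3"), NULL))
  slm <- new("SiteLogLikelihoodMatrix", values = V,
             partitionIndex = rep(1L, 80))
  R <- rellReplicates(slm, B = 20000, seed = 2)
  obs <- rowSums(V)
  # replicate totals have sd ~ sqrt(N) * site sd; the mean over B
  # replicates converges to the observed total (law of large numbers)
  se <- sqrt(ncol(V)) * apply(V, 1, sd) / sqrt(20000)
  for (i in 1:3)
    expect_lt(abs(mean(R[i, ]) - obs[i]), 3 * se[i])
  # identical rows give identical replicate totals
  V2 <- rbind(V[1, ], V[1, ])
  rownames(V2) <- c("a", "b")
  R2 <- rellReplicates(new("SiteLogLikelihoodMatrix", values = V2,
                           partitionIndex = rep(1L, 80)), B = 50, seed = 4)
  expect_equal(R2[1, ], R2[2, ])
  expect_identical(rellReplicates(slm, 20, seed = 6),
                   rellReplicates(slm, 20, seed = 6))
})

test_that("SH test gives p = 1 to the best topology and is exchangeable", {
  set.seed(11)
  V <- matrix(rnorm(2 * 60, -2), 2, 60, dimnames = list(c("a", "b"), NULL))
  V[2, ] <- V[1, ]                      # identical site likelihoods
  slm <- new("SiteLogLikelihoodMatrix", values = V,
             partitionIndex = rep(1L, 60))
  r <- shTest(slm, B = 5000, seed = 1)
  expect_true(all(r@table$pSH >= 0.95))
  expect_equal(r@table$pSH[which.max(r@table$logLik)], 1)
  # a clearly better topology keeps p = 1; the worse one drops
  V[2, ] <- V[1, ] - 0.4
  slm2 <- new("SiteLogLikelihoodMatrix", values = V,
              partitionIndex = rep(1L, 60))
  r2 <- shTest(slm2, B = 5000, seed = 1)
  expect_equal(r2@table$pSH[1], 1)
  expect_lt(r2@table$pSH[2], 0.1)
  expect_warning(shTest(new("SiteLogLikelihoodMatrix",
                            values = V[1, , drop = FALSE],
                            partitionIndex = rep(1L, 60)), B = 100),
                 "single topology")
})

test_that("SH agrees with an independent naive implementation", {
  set.seed(17)
  V <- matrix(rnorm(3 * 50, -2, 0.6), 3, 50,
              dimnames = list(c("t1", "t2", "t3"), NULL))
  V[2, ] <- V[2, ] - 0.05
  V[3, ] <- V[3, ] - 0.15
  slm <- new("SiteLogLikelihoodMatrix", values = V,
             partitionIndex = rep(1L, 50))
  mine <- shTest(slm, B = 20000, seed = 3)@table$pSH
  ref <- naiveSH(V, B = 20000, seed = 99)
  se <- sqrt(ref * (1 - ref) / 20000)
  expect_true(all(abs(mine - ref) < pmax(4 * se, 0.01)))
})

test_that("AU test is symmetric for exchangeable topologies and flags
           degenerate winners", {
  set.seed(23)
  base <- rnorm(400, -2, 0.5)
  V <- rbind(a = base, b = base)        # identical site log-likelihoods
  slm <- new("SiteLogLikelihoodMatrix", values = V,
             partitionIndex = rep(1L, 400))
  r <- auTest(slm, B = 4000, seed = 2)
  expect_true(all(abs(r@table$pAU - 0.5) < 0.1))
  # a topology that wins every replicate at every scale
  V2 <- rbind(good = base, bad = base - 1)
  r2 <- auTest(new("SiteLogLikelihoodMatrix", values = V2,
                   partitionIndex = rep(1L, 400)), B = 500, seed = 5)
  expect_equal(r2@table$pAU[r2@table$id == "good"], 1)
  expect_equal(r2@table$auFlag[r2@table$id == "good"], "degenerate-high")
  expect_equal(r2@table$pAU[r2@table$id == "bad"], 0)
})

test_that("composition chi-square matches hand computation and direction", {
  # hand toy: taxon observes [6, 4] against expected [5, 5] -> X^2 = 0.4
  s1 <- paste(c(rep("A", 6), rep("C", 4)), collapse = "")
  s2 <- paste(c(rep("A", 4), rep("C", 6)), collapse = "")
  aln <- partitionedAlignment(c(a = s1, b = s2), "nt")
  tab <- compositionChisq(aln)
  expect_equal(tab$statistic, c(0.4, 0.4), tolerance = 1e-12)
  expect_equal(tab$df, c(3L, 3L))       # 4 nucleotide states - 1
  # identical sequences: statistic 0, p = 1
  aln0 <- partitionedAlignment(c(a = "ACGT", b = "ACGT", c = "ACGT"), "nt")
  tab0 <- compositionChisq(aln0)
  expect_equal(tab0$statistic, rep(0, 3))
  expect_equal(tab0$p, rep(1, 3))
  # a deviant taxon gets a large statistic and small p
  sk <- c(a = paste(rep("A", 60), collapse = ""),
          b = paste(rep(c("G", "C"), 30), collapse = ""),
          c = paste(rep(c("G", "C"), 30), collapse = ""))
  tabs <- compositionChisq(partitionedAlignment(sk, "nt"))
  expect_lt(tabs$p[1], 0.001)
  expect_gt(tabs$statistic[1], tabs$statistic[2])
  # missing sites are ignored in the counts
  gap <- partitionedAlignment(c(a = "AC--", b = "ACGT"), "nt")
  expect_equal(compositionChisq(gap)$df, c(3L, 3L))
  expect_error(compositionChisq(partitionedAlignment(c(a = "--", b = "AC"),
                                                     "nt")),
               "zero non-missing")
})
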