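test_that("root attachment enumeration covers all 2n-3 branches", {
  set.seed(3)
  for (n in c(4, 6, 9)) {
    phy <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 0.3)))
    cand <- enumerateRootAttachments(phy)
    expect_equal(nrow(cand), 2 * n - 3)
    expect_equal(anyDuplicated(cand$split), 0L)
    keys <- rootgraft:::.bipartitionKeys(phy, trivial = TRUE)
    for (s in cand$split) {
      side <- strsplit(s, ",", fixed = TRUE)[[1]]
      expect_true(rootgraft:::.bipartKey(side, phy$tip.label) %in% keys)
    }
  }
})

test_that("a named subset restricts and labels the candidates", {
  set.seed(8)
  phy <- ape::unroot(ape::rtree(7, br = function(k) runif(k, 0.1, 0.3)))
  all11 <- enumerateRootAttachments(phy)
  expect_equal(nrow(all11), 11L)        # 2*7 - 3
  subset <- lapply(all11$split, function(s)
    strsplit(s, ",", fixed = TRUE)[[1]])
  names(subset) <- letters[seq_len(11)]
  cand <- enumerateRootAttachments(phy, subset = subset)
  expect_equal(nrow(cand), 11L)
  expect_equal(cand$id, letters[1:11])
  expect_error(enumerateRootAttachments(phy,
                                        subset = list(z = c("zzz", "yyy"))),
               "not present")
})

test_that("graft and classify are inverse for every branch", {
  set.seed(21)
  for (rep in 1:3) {
    n <- sample(5:8, 1)
    phy <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 0.3)))
    groups <- as.list(setNames(phy$tip.label, phy$tip.label))
    cand <- enumerateRootAttachments(phy)
    for (ci in seq_len(nrow(cand))) {
      full <- graftOutgroup(phy, cand$edge[ci], c("og1", "og2"),
                            stemLength = 0.4)
      expect_setequal(full$tip.label, c(phy$tip.label, "og1", "og2"))
      # grafting keeps the tree binary (unrooted degree-3 internals)
      tabn <- tabulate(c(full$edge), nbins = length(full$tip.label) +
                         full$Nnode)
      expect_true(all(tabn[-(seq_along(full$tip.label))] %in% c(2L, 3L)))
      cls <- classifyRootPosition(full, phy$tip.label, groups)
      side <- strsplit(cand$split[ci], ",", fixed = TRUE)[[1]]
      expect_true(setequal(cls$sideA, side) || setequal(cls$sideB, side))
      expect_false(cls$flagged)
    }
  }
})

test_that("grafting a terminal branch makes the outgroup its sister", {
  phy <- parseNewick("((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  phy <- ape::unroot(phy)
  cand <- enumerateRootAttachments(phy)
  term <- cand[cand$split == "a", ]
  full <- graftOutgroup(phy, term$edge, "og", stemLength = 0.3)
  expect_true(isMonophyletic(full, c("a", "og")))
})

test_that("group labels name deep splits and stems sensibly", {
  groups <- list(A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2"))
  id1 <- rootgraft:::.rootIdFromSplit(c("a1", "a2"),
                                      c("b1", "b2", "c1", "c2"), groups)
  expect_equal(id1, "A")
  id2 <- rootgraft:::.rootIdFromSplit(c("a1", "a2", "b1", "b2"),
                                      c("c1", "c2"), groups)
  expect_equal(id2, "C")
  id3 <- rootgraft:::.rootIdFromSplit(c("a1", "b1"),
                                      c("a2", "b2", "c1", "c2"), groups)
  expect_match(id3, "^split:")
})

test_that("root scan ranks candidates, flags the best and sizes the table", {
  set.seed(33)
  sc <- parabasaliaScenario(scenarioParams(
    groupSizes = c(C = 2L, S = 2L, Tn = 2L, Tt = 2L, H = 2L, Tm = 2L),
    outgroupSize = 2L, widths = c(nt1 = 300L), models = "GTR+G4"),
    seed = 14)
  aln <- simulateScenarioAlignment(sc, seed = 15)
  ing <- ape::unroot(ape::drop.tip(sc$tree, sc$outgroupTaxa))
  rs <- rootScan(ing, aln, NULL, sc$outgroupTaxa, groups = sc$groups,
                 Bsh = 1000, Bau = 1000, seed = 5, tol = 1e-1)
  expect_equal(nrow(rs@candidates), 2 * 12 - 3)
  expect_true(all(c("pSH", "pAU") %in% names(rs@candidates)))
  best <- rs@candidates[rs@candidates$id == rs@bestId, ]
  expect_equal(best$deltaLnL, 0)
  expect_equal(best$pSH, 1)
  # unconstrained ML over the full data is at least as good as any graft
  free <- mlSearch(aln, NULL, searchConfig(tol = 1e-2))
  expect_gte(free@logLik + 1e-6, max(rs@candidates$logLik))

  # single-candidate scan: that candidate is best with p = 1
  cand1 <- enumerateRootAttachments(ing)[1, ]
  expect_warning(rs1 <- rootScan(ing, aln, NULL, sc$outgroupTaxa,
                                 candidates = cand1, groups = sc$groups,
                                 Bsh = 200, Bau = 200, seed = 1,
                                 tol = 1e-1),
                 "single topology")
  expect_equal(nrow(rs1@candidates), 1L)
  expect_equal(rs1@candidates$pSH, 1)
})

test_that("constrained pairing tests enumerate exactly the absent pairs", {
  set.seed(44)
  # 4 groups of 2 on a (((A,B),(C,D))) style tree: pairs A+B and C+D are
  # present, so choose(4,2) - 2 = 4 pairings get tested
  groups <- list(A = c("a1", "a2"), B = c("b1", "b2"),
                 C = c("c1", "c2"), D = c("d1", "d2"))
  nwk <- "(((a1:0.05,a2:0.05):0.1,(b1:0.05,b2:0.05):0.1):0.08,((c1:0.05,c2:0.05):0.1,(d1:0.05,d2:0.05):0.1):0.08);"
  tr <- parseNewick(nwk)
  m <- gtrModel(shape = NA, nCat = 1L)
  aln <- simulateAlignment(tr, m, 400, seed = 4)
  mlFit <- optimizeBranchLengths(tr, aln, m, tol = 1e-2)
  res <- constraintPairTests(aln, m, groups, mlFit = mlFit,
                             config = searchConfig(tol = 1e-1),
                             Bsh = 500, Bau = 500, seed = 2)
  expect_equal(nrow(res$table), choose(4, 2) - 2)
  expect_false(any(c("A+B", "C+D") %in% res$table$pair))
  expect_true(all(res$table$logLik <= mlFit@logLik + 1e-6))
  for (id in res$table$pair) {
    prs <- strsplit(id, "+", fixed = TRUE)[[1]]
    expect_true(isMonophyletic(res$fits[[id]]@tree,
                               c(groups[[prs[1]]], groups[[prs[2]]])))
  }
})

test_that("long-branch outgroup removal reruns the analysis per step", {
  set.seed(55)
  sc <- parabasaliaScenario(scenarioParams(
    groupSizes = c(C = 2L, S = 2L, Tn = 2L, Tt = 2L, H = 2L, Tm = 2L),
    outgroupSize = 3L, widths = c(nt1 = 250L), models = "GTR+G4"),
    seed = 8)
  aln <- simulateScenarioAlignment(sc, seed = 9)
  res <- longbranchRemovalSeries(aln, NULL, sc$outgroupTaxa,
                                 schedule = c(1L), groups = sc$groups,
                                 config = searchConfig(tol = 1e-1))
  expect_equal(nrow(res), 2L)           # full analysis + one removal step
  expect_equal(res$nRemoved, c(0L, 1L))
  expect_true(all(nzchar(res$rootId)))
  expect_error(longbranchRemovalSeries(aln, NULL, sc$outgroupTaxa,
                                       schedule = 3L, groups = sc$groups),
               "empty the outgroup")
})
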