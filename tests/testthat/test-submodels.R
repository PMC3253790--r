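test_that("rate matrix construction is normalized and reversible", {
  # all-ones exchangeabilities with uniform frequencies give JC69
  S <- matrix(1, 4, 4); diag(S) <- 0
  Q <- buildRateMatrix(S, rep(0.25, 4))
  expect_equal(Q[1, 2], 1 / 3, tolerance = 1e-12)
  expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12)
  expect_equal(-sum(0.25 * diag(Q)), 1, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:10) {
    k <- sample(c(4L, 20L), 1)
    S <- matrix(0, k, k)
    S[lower.tri(S)] <- runif(k * (k - 1) / 2, 0.1, 3)
    S <- S + t(S)
    pi <- randomSimplex(k)
    Q <- buildRateMatrix(S, pi)
    expect_equal(rowSums(Q), rep(0, k), tolerance = 1e-12)
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    # detailed balance pi_i Q_ij = pi_j Q_ji
    expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-12)
  }
  expect_error(buildRateMatrix(matrix(c(0, 1, 2, 0), 2), c(0.5, 0.5)),
               "symmetric")
})

test_that("transition probabilities match the JC closed form and CK", {
  jc <- gtrModel(shape = NA, nCat = 1L)
  expect_equal(unname(transitionProbabilities(jc, 0)), diag(4),
               tolerance = 1e-12)
  for (t in c(0.01, 0.1, 0.7, 2.5)) {
    P <- transitionProbabilities(jc, t)
    expect_equal(unname(diag(P)), rep(1 / 4 + 3 / 4 * exp(-4 * t / 3), 4),
                 tolerance = 1e-10)
    expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-10)
  }
  # long-time limit: rows -> stationary frequencies
  m <- randomGtr()
  Pinf <- transitionProbabilities(m, 500)
  for (r in 1:4) expect_equal(unname(Pinf[r, ]), unname(m@freqs),
                              tolerance = 1e-8)
  # Chapman-Kolmogorov P(s+t) = P(s) P(t)
  set.seed(3)
  for (i in 1:5) {
    mm <- if (i %% 2) randomGtr() else randomWag()
    s <- runif(1, 0.01, 1); t <- runif(1, 0.01, 1)
    expect_lt(max(abs(transitionProbabilities(mm, s + t) -
                      transitionProbabilities(mm, s) %*%
                      transitionProbabilities(mm, t))), 1e-8)
  }
})

test_that("discrete-gamma category rates match a quadrature oracle", {
  expect_identical(discretizeGamma(0.7, 1), 1)
  # degenerate limit: conditional quartile means deviate by ~1.27/sqrt(a)
  expect_true(all(abs(discretizeGamma(1e7, 4) - 1) < 1e-3))
  for (alpha in c(0.5, 1, 2.3)) {
    k <- 4L
    qb <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
    oracle <- vapply(seq_len(k), function(i) {
      integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                qb[i], qb[i + 1], rel.tol = 1e-10)$value * k
    }, numeric(1))
    oracle <- oracle / mean(oracle)
    expect_equal(discretizeGamma(alpha, k), oracle, tolerance = 1e-6)
    expect_equal(mean(discretizeGamma(alpha, k)), 1, tolerance = 1e-14)
  }
})

test_that("WAG model constants are a valid reversible amino-acid model", {
  w <- wagModel()
  expect_equal(sum(w@freqs), 1, tolerance = 1e-10)
  expect_equal(length(w@freqs), 20L)
  Q <- buildRateMatrix(w@exch, w@freqs)
  expect_lt(max(abs(w@freqs * Q - t(w@freqs * Q))), 1e-12)
  skip_if_not_installed("phangorn")
  ref <- get(".WAG", envir = asNamespace("phangorn"))
  expect_equal(unname(w@exch[lower.tri(w@exch)]), ref$Q, tolerance = 1e-5)
  expect_equal(unname(w@freqs), unname(ref$bf / sum(ref$bf)),
               tolerance = 1e-5)
})

test_that("empirical amino-acid frequencies use pseudocounts", {
  aln <- partitionedAlignment(c(a = "AAAA", b = "AAAA"), "aa")
  w <- wagModel(freqMode = "empirical", aln = aln)
  expect_equal(which.max(w@freqs), c(A = 1L))
  expect_true(all(w@freqs > 0))
  expect_error(wagModel(freqMode = "empirical",
                        aln = partitionedAlignment(c(a = "--", b = "--"),
                                                   "aa")),
               "empty")
})

test_that("GTR parameterization round-trips and favors set exchanges", {
  m1 <- gtrModel()  # all rates 1, uniform: JC
  expect_equal(buildRateMatrix(m1@exch, m1@freqs)[1, 2], 1 / 3,
               tolerance = 1e-12)
  rates <- c(1.3, 4, 0.7, 0.9, 5, 1)
  m2 <- gtrModel(rates = rates, freqs = c(0.3, 0.2, 0.2, 0.3))
  m3 <- gtrModel(rates = rootgraft:::.gtrRateVector(m2), freqs = m2@freqs)
  expect_equal(m2@exch, m3@exch, tolerance = 1e-12)
  # transition-heavy model concentrates A<->G and C<->T changes
  tv <- gtrModel(rates = c(1, 20, 1, 1, 20, 1), shape = NA, nCat = 1L)
  P <- transitionProbabilities(tv, 0.3)
  expect_gt(P["A", "G"], 3 * max(P["A", "C"], P["A", "T"]))
  expect_gt(P["C", "T"], 3 * max(P["C", "A"], P["C", "G"]))
})

test_that("model tags parse to the right configuration", {
  expect_equal(modelFromTag("GTR+G4")@nCat, 4L)
  expect_equal(modelFromTag("WAG+G4")@alphabet, "aa")
  expect_true(is.na(modelFromTag("GTR")@gammaShape))
  aln <- partitionedAlignment(c(a = "MMMM", b = "MMMM"), "aa")
  mf <- modelFromTag("WAG+G4+F", aln = aln)
  expect_equal(unname(which.max(mf@freqs)), match("M", mf@states))
  expect_error(modelFromTag("HKY+G4"), "unknown model")
})
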