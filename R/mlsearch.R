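## Maximum-likelihood estimation: branch lengths by exact per-edge
## coordinate ascent (inside/outside partials), model parameters by
## bounded 1-D ascent, topology by best-improvement NNI hill climbing with
## optional monophyly constraints.

.BRLEN_BOUNDS <- c(1e-8, 10)

# children of each node, in edge-row order, plus edge row per child
.phyloChildren <- function(phy) {
  nn <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1]]] <- c(kids[[phy$edge[i, 1]]], phy$edge[i, 2])
  kids
}

.preorderNodes <- function(phy) {
  kids <- .phyloChildren(phy)
  root <- length(phy$tip.label) + 1L
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, rev(kids[[v]]))
  }
  out[out > length(phy$tip.label)]
}

# Pairwise Poisson-corrected distances on co-observed sites.
.pairwiseDistances <- function(aln) {
  m <- aln@seqs
  idx <- .partitionIndex(aln)
  p <- aln@partitions
  obs <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(p))) {
    sel <- .partitionSites(p, i)
    obs[, sel] <- !.isMissingChar(m[, sel, drop = FALSE], p$alphabet[i])
  }
  nt <- nrow(m)
  D <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nt - 1L)) for (j in seq.int(i + 1L, nt)) {
    co <- obs[i, ] & obs[j, ]
    if (!any(co))
      stop("taxon pair with zero co-observed sites: ", rownames(m)[i], " / ",
           rownames(m)[j], call. = FALSE)
    pdist <- mean(m[i, co] != m[j, co])
    D[i, j] <- D[j, i] <- -log(1 - min(pdist, 0.95))
  }
  D
}

#' Neighbor-joining starting tree
#'
#' NJ on pairwise normalized Hamming distances restricted to co-observed
#' sites, with a Poisson correction -log(1 - p) (p capped at 0.95);
#' negative NJ branch lengths are clamped to 1e-6.
#'
#' @param aln a \code{PartitionedAlignment} with >= 3 taxa.
#' @return an unrooted \code{ape::phylo}.
#' @export
buildStartTree <- function(aln) {
  .assert(nrow(aln@seqs) >= 3L, "need at least 3 taxa")
  D <- .pairwiseDistances(aln)
  if (nrow(D) == 3L) {
    # NJ needs >= 4 tips; the 3-taxon star is the unique unrooted topology
    d <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
           (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
           (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    d <- pmax(d, 1e-6)
    return(parseNewick(sprintf("(%s:%g,%s:%g,%s:%g);", rownames(D)[1], d[1],
                               rownames(D)[2], d[2], rownames(D)[3], d[3])))
  }
  phy <- ape::nj(D)
  phy$edge.length[phy$edge.length < 1e-6] <- 1e-6
  .unrootedBinary(phy)
}

## ---- per-partition engines & totals ------------------------------------

.resolveModels <- function(aln, models = NULL) {
  p <- aln@partitions
  if (is.null(models)) models <- p$model
  if (is(models, "RateModel")) models <- rep(list(models), nrow(p))
  if (is.character(models))
    models <- lapply(seq_along(models),
                     function(i) modelFromTag(models[i], aln = aln))
  .assert(length(models) == nrow(p), "one model per partition required")
  for (i in seq_len(nrow(p)))
    .assert(models[[i]]@alphabet == p$alphabet[i],
            sprintf("model %d alphabet does not match partition", i))
  models
}

.buildEngines <- function(aln, models) {
  lapply(seq_len(nrow(aln@partitions)), function(i)
    .likEngine(.partitionMatrix(aln, i), models[[i]]))
}

.patternTotal <- function(phy, engine, edgeLen) {
  sum(.patternLogLik(phy, engine, edgeLen) * engine$patWeights)
}

.totalLnL <- function(phy, engines, edgeLens) {
  sum(vapply(seq_along(engines), function(i)
    .patternTotal(phy, engines[[i]], edgeLens[[i]]), numeric(1)))
}

## ---- exact per-edge branch-length objective -----------------------------

# child "message" toward parent: M = P %*% (scaled child partial);
# tips use indicator columns of P.  Returns list(M, sc).
.childMessage <- function(phy, engine, edgeLen, rate, e, down) {
  n <- length(phy$tip.label)
  ch <- phy$edge[e, 2]
  P <- .pmat(engine$eig, edgeLen[e] * rate)
  if (ch <= n) {
    cd <- engine$codes[match(phy$tip.label[ch], engine$taxa), ]
    M <- matrix(1, engine$k, ncol(engine$codes))
    obs <- which(!is.na(cd))
    M[, obs] <- P[, cd[obs]]
    list(M = M, sc = numeric(ncol(engine$codes)))
  } else {
    pc <- down$partial[[ch]]
    s <- .rowMax(pc); s[s == 0] <- 1
    list(M = P %*% (pc / rep(s, each = engine$k)),
         sc = down$scaler[[ch]] + log(s))
  }
}

# scaled down-partial of an edge's child (D side of the edge objective)
.childD <- function(phy, engine, e, down) {
  n <- length(phy$tip.label)
  ch <- phy$edge[e, 2]
  if (ch <= n) {
    cd <- engine$codes[match(phy$tip.label[ch], engine$taxa), ]
    D <- matrix(0, engine$k, ncol(engine$codes))
    obs <- which(!is.na(cd))
    D[cbind(cd[obs], obs)] <- 1
    D[, setdiff(seq_len(ncol(D)), obs)] <- 1
    list(D = D, sc = numeric(ncol(engine$codes)))
  } else {
    pc <- down$partial[[ch]]
    s <- .rowMax(pc); s[s == 0] <- 1
    list(D = pc / rep(s, each = engine$k), sc = down$scaler[[ch]] + log(s))
  }
}

# Optimize the length of edge e given per-category outside vectors O
# (with log-scalers scO) and child partials D (with scalers scD); exact
# 1-D likelihood in t, maximized by Brent in log space.
.optimizeEdge1 <- function(parts, w, bounds, brTol, t0) {
  # parts: list per (engine) of list(cat -> list(O, scO, D, scD, eig, rate,
  # weight, patWeights))
  f <- function(logt) {
    t <- exp(logt)
    tot <- 0
    for (pp in parts) {
      lv <- matrix(NA_real_, length(pp$cats), length(pp$cats[[1]]$scO))
      for (ci in seq_along(pp$cats)) {
        cc <- pp$cats[[ci]]
        P <- .pmat(pp$eig, t * cc$rate)
        v <- colSums(cc$O * (P %*% cc$D))
        v[v <= 0] <- .Machine$double.xmin
        lv[ci, ] <- log(v) + cc$scO + cc$scD + log(cc$weight)
      }
      tot <- tot + sum(.colLogSumExp(lv) * pp$patWeights)
    }
    tot
  }
  lo <- log(bounds[1]); hi <- log(bounds[2])
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = brTol)
  cand <- c(opt$maximum, lo, log(max(t0, bounds[1])))
  vals <- c(opt$objective, f(lo), f(log(max(t0, bounds[1]))))
  best <- which.max(vals)
  list(t = exp(cand[best]), lnL = vals[best])
}

# One full coordinate-ascent sweep over all edges for one partition.
# Exact per-edge objectives (fresh inside/outside partials); returns the
# updated edge lengths.
.blSweepOnePartition <- function(phy, engine, edgeLen, bounds, brTol) {
  n <- length(phy$tip.label)
  root <- n + 1L
  k <- engine$k
  npat <- ncol(engine$codes)
  ncat <- length(engine$rates)
  kids <- .phyloChildren(phy)
  edgeRowOf <- integer(n + phy$Nnode)
  edgeRowOf[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  down <- lapply(engine$rates, function(r) .downPartials(phy, engine, edgeLen, r))
  A <- vector("list", n + phy$Nnode)    # outside vector at node, per cat
  scA <- vector("list", n + phy$Nnode)
  A[[root]] <- lapply(seq_len(ncat),
                      function(ci) matrix(engine$freqs, k, npat))
  scA[[root]] <- lapply(seq_len(ncat), function(ci) numeric(npat))
  for (p in .preorderNodes(phy)) {
    ch <- kids[[p]]
    if (is.null(A[[p]])) next
    msgs <- lapply(seq_len(ncat), function(ci)
      lapply(ch, function(c2) .childMessage(phy, engine, edgeLen,
                                            engine$rates[ci],
                                            edgeRowOf[c2], down[[ci]])))
    for (i in seq_along(ch)) {
      e <- edgeRowOf[ch[i]]
      cats <- vector("list", ncat)
      for (ci in seq_len(ncat)) {
        O <- A[[p]][[ci]]
        scO <- scA[[p]][[ci]]
        for (j in seq_along(ch)) if (j != i) {
          O <- O * msgs[[ci]][[j]]$M
          scO <- scO + msgs[[ci]][[j]]$sc
        }
        cd <- .childD(phy, engine, e, down[[ci]])
        cats[[ci]] <- list(O = O, scO = scO, D = cd$D, scD = cd$sc,
                           rate = engine$rates[ci],
                           weight = engine$weights[ci])
      }
      opt <- .optimizeEdge1(list(list(cats = cats, eig = engine$eig,
                                      patWeights = engine$patWeights)),
                            NULL, bounds, brTol, edgeLen[e])
      edgeLen[e] <- opt$t
      # refresh this child's message with the new length
      for (ci in seq_len(ncat))
        msgs[[ci]][[i]] <- .childMessage(phy, engine, edgeLen,
                                         engine$rates[ci], e, down[[ci]])
    }
    # outside vectors for internal children, with final sibling messages
    for (i in seq_along(ch)) {
      c2 <- ch[i]
      if (c2 <= n) next
      e <- edgeRowOf[c2]
      A[[c2]] <- vector("list", ncat)
      scA[[c2]] <- vector("list", ncat)
      for (ci in seq_len(ncat)) {
        O <- A[[p]][[ci]]
        scO <- scA[[p]][[ci]]
        for (j in seq_along(ch)) if (j != i) {
          O <- O * msgs[[ci]][[j]]$M
          scO <- scO + msgs[[ci]][[j]]$sc
        }
        P <- .pmat(engine$eig, edgeLen[e] * engine$rates[ci])
        Anew <- crossprod(P, O)
        s <- .rowMax(Anew); s[s == 0] <- 1
        A[[c2]][[ci]] <- Anew / rep(s, each = k)
        scA[[c2]][[ci]] <- scO + log(s)
      }
    }
  }
  edgeLen
}

# Branch lengths for one partition until the lnL gain drops below tol.
.optimizeBlOnePartition <- function(phy, engine, edgeLen, tol = 1e-3,
                                    maxSweeps = 20L,
                                    bounds = .BRLEN_BOUNDS, brTol = 1e-6) {
  cur <- .patternTotal(phy, engine, edgeLen)
  for (s in seq_len(maxSweeps)) {
    newLen <- .blSweepOnePartition(phy, engine, edgeLen, bounds, brTol)
    new <- .patternTotal(phy, engine, newLen)
    if (new >= cur) { edgeLen <- newLen }
    if (new - cur < tol) { cur <- max(new, cur); break }
    cur <- new
  }
  list(edgeLen = edgeLen, logLik = cur, sweeps = s)
}

## ---- model parameter optimization ---------------------------------------

.engineWithShape <- function(engine, model, shape) {
  rw <- .modelRatesWeights(.withShape(model, shape))
  engine$rates <- rw$rates
  engine$weights <- rw$weights
  engine
}

.engineWithModel <- function(engine, model) {
  rw <- .modelRatesWeights(model)
  Q <- buildRateMatrix(model@exch, model@freqs)
  engine$eig <- .eigenRateMatrix(Q, model@freqs)
  engine$freqs <- model@freqs
  engine$rates <- rw$rates
  engine$weights <- rw$weights
  engine
}

# Per-partition alpha (and GTR exchangeabilities) by bounded 1-D ascent,
# alternated with branch-length sweeps by the caller.
.optimizeModelOnePartition <- function(phy, engine, model, edgeLen,
                                       tol = 1e-3) {
  if (!is.na(model@gammaShape) && model@nCat > 1L) {
    f <- function(la) .patternTotal(phy, .engineWithShape(engine, model,
                                                          exp(la)), edgeLen)
    opt <- optimize(f, log(c(0.02, 100)), maximum = TRUE, tol = 1e-3)
    if (opt$objective > .patternTotal(phy, engine, edgeLen)) {
      model <- .withShape(model, exp(opt$maximum))
      engine <- .engineWithShape(engine, model, model@gammaShape)
    }
  }
  if (model@alphabet == "nt") {
    rates <- .gtrRateVector(model)
    for (ri in 1:5) {   # G-T rate is the fixed reference
      f <- function(lr) {
        r2 <- rates; r2[ri] <- exp(lr)
        .patternTotal(phy, .engineWithModel(engine, .withGtrRates(model, r2)),
                      edgeLen)
      }
      opt <- optimize(f, log(c(1e-3, 1e3)), maximum = TRUE, tol = 1e-3)
      r2 <- rates; r2[ri] <- exp(opt$maximum)
      if (opt$objective >= .patternTotal(phy, engine, edgeLen)) {
        rates <- r2
        model <- .withGtrRates(model, rates)
        engine <- .engineWithModel(engine, model)
      }
    }
  }
  list(model = model, engine = engine)
}

## ---- the partitioned fit -------------------------------------------------

.initEdgeLens <- function(phy, nPart) {
  el <- phy$edge.length
  if (is.null(el)) el <- rep(0.1, nrow(phy$edge))
  el <- pmin(pmax(el, .BRLEN_BOUNDS[1]), .BRLEN_BOUNDS[2])
  rep(list(el), nPart)
}

# Full fit of branch lengths (per partition) and optionally model
# parameters on a fixed topology.
.fitTopology <- function(phy, aln, models, engines = NULL,
                         edgeLens = NULL, tol = 1e-3, optimizeModel = FALSE,
                         maxRounds = 4L, brTol = 1e-6, maxSweeps = 20L) {
  phy <- .unrootedBinary(phy)
  .assert(setequal(phy$tip.label, rownames(aln@seqs)),
          "tree leaves and alignment taxa differ")
  if (is.null(engines)) engines <- .buildEngines(aln, models)
  if (is.null(edgeLens)) edgeLens <- .initEdgeLens(phy, length(engines))
  total <- .totalLnL(phy, engines, edgeLens)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    for (i in seq_along(engines)) {
      r <- .optimizeBlOnePartition(phy, engines[[i]], edgeLens[[i]],
                                   tol = tol, brTol = brTol,
                                   maxSweeps = maxSweeps)
      edgeLens[[i]] <- r$edgeLen
    }
    if (optimizeModel)
      for (i in seq_along(engines)) {
        r <- .optimizeModelOnePartition(phy, engines[[i]], models[[i]],
                                        edgeLens[[i]], tol = tol)
        models[[i]] <- r$model
        engines[[i]] <- r$engine
      }
    new <- .totalLnL(phy, engines, edgeLens)
    if (new - total < tol || rounds >= maxRounds) { total <- max(new, total); break }
    total <- new
  }
  list(phy = phy, models = models, engines = engines, edgeLens = edgeLens,
       logLik = total, rounds = rounds)
}

.asFit <- function(state, aln, seed = NA_real_) {
  sll <- numeric(nSites(aln))
  p <- aln@partitions
  for (i in seq_along(state$engines))
    sll[.partitionSites(p, i)] <-
      .partitionSiteLogLik(state$phy, state$engines[[i]], state$edgeLens[[i]])
  tree <- state$phy
  tree$edge.length <- state$edgeLens[[1]]
  new("PartitionedModelFit", tree = tree, edgeLengths = state$edgeLens,
      models = state$models, partitions = p,
      logLik = state$logLik, siteLogLik = sll,
      details = list(alpha = vapply(state$models, slot, numeric(1),
                                    "gammaShape"),
                     rounds = state$rounds, seed = seed))
}

#' Optimize branch lengths on a fixed topology
#'
#' Per-partition branch lengths (fully unlinked across partitions) by
#' exact per-edge coordinate ascent: for every edge the 1-D likelihood in
#' that edge's length is maximized by Brent search in log space within
#' [1e-8, 10], sweeping all edges until the total log-likelihood gain per
#' sweep falls below \code{tol}.  The total log-likelihood never
#' decreases.
#'
#' @param tree fixed topology (\code{ape::phylo}); rooted input is
#'   unrooted first.
#' @param aln the partitioned alignment.
#' @param models per-partition models (\code{RateModel}, list thereof, tag
#'   strings, or NULL to use the scheme's tags).
#' @param tol convergence tolerance in log-likelihood units.
#' @param optimizeModel also optimize gamma shapes (and GTR rates).
#' @return a \code{PartitionedModelFit}.
#' @export
optimizeBranchLengths <- function(tree, aln, models = NULL, tol = 1e-3,
                                  optimizeModel = FALSE) {
  models <- .resolveModels(aln, models)
  .asFit(.fitTopology(tree, aln, models, tol = tol,
                      optimizeModel = optimizeModel), aln)
}

#' Optimize model parameters of an existing fit
#'
#' Per partition, the gamma shape (bounded in [0.02, 100]) and, for
#' nucleotide partitions, the five free GTR exchangeabilities (G-T fixed
#' at 1 as reference) are optimized by bounded coordinate ascent,
#' interleaved with branch-length sweeps until the joint tolerance is met.
#'
#' @param fit a \code{PartitionedModelFit}.
#' @param aln the alignment it was fitted to.
#' @param tol convergence tolerance in log-likelihood units.
#' @return an updated \code{PartitionedModelFit}.
#' @export
optimizeModelParameters <- function(fit, aln, tol = 1e-3) {
  models <- fit@models
  .asFit(.fitTopology(fit@tree, aln, models, edgeLens = fit@edgeLengths,
                      tol = tol, optimizeModel = TRUE), aln,
         seed = fit@details$seed)
}

## ---- NNI neighborhood ----------------------------------------------------

#' Nearest-neighbor-interchange neighborhood
#'
#' All NNI rearrangements of an unrooted binary tree: exactly two per
#' internal branch, 2(n-3) in total, enumerated in a fixed preorder of the
#' internal edges so that search runs are deterministic.  Branch lengths
#' are carried over unchanged (each subtree keeps its stem length).
#'
#' @param phy unrooted binary tree with >= 4 tips.
#' @return list of \code{phylo} trees.
#' @export
nniNeighbors <- function(phy) {
  phy <- .unrootedBinary(phy)
  n <- length(phy$tip.label)
  .assert(n >= 4L, "need >= 4 taxa")
  phy <- ape::reorder.phylo(phy, "cladewise")
  kids <- .phyloChildren(phy)
  root <- n + 1L
  edgeRowOf <- integer(n + phy$Nnode)
  edgeRowOf[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  out <- list()
  for (e in seq_len(nrow(phy$edge))) {
    v <- phy$edge[e, 2]
    if (v <= n) next                    # internal edges only
    u <- phy$edge[e, 1]
    w <- setdiff(kids[[u]], v)[1]       # a fixed neighbor of u besides v
    for (ci in 1:2) {
      cc <- kids[[v]][ci]
      t2 <- phy
      ea <- edgeRowOf[w]; eb <- edgeRowOf[cc]
      t2$edge[ea, 2] <- cc
      t2$edge[eb, 2] <- w
      if (!is.null(t2$edge.length))
        t2$edge.length[c(ea, eb)] <- t2$edge.length[c(eb, ea)]
      attr(t2, "order") <- NULL
      out[[length(out) + 1L]] <- t2
    }
  }
  out
}

# apply the same child swap to per-partition edge length vectors
.swapEdgeLens <- function(edgeLens, phyOld, phyNew) {
  ch <- which(phyOld$edge[, 2] != phyNew$edge[, 2])
  if (length(ch) == 0L) return(edgeLens)
  lapply(edgeLens, function(el) { el[ch] <- el[rev(ch)]; el })
}

## ---- tree search ---------------------------------------------------------

# quick lnL of a neighbor: carried lengths, no optimization
.quickEval <- function(phy, engines, edgeLens) .totalLnL(phy, engines, edgeLens)

# optimize only edge e (all partitions), return new lengths and total lnL
.optimizeCentralEdge <- function(phy, engines, edgeLens, e) {
  n <- length(phy$tip.label)
  for (i in seq_along(engines)) {
    engine <- engines[[i]]
    edgeLen <- edgeLens[[i]]
    ncat <- length(engine$rates)
    down <- lapply(engine$rates,
                   function(r) .downPartials(phy, engine, edgeLen, r))
    # outside vectors along the path root -> parent of e
    kids <- .phyloChildren(phy)
    edgeRowOf <- integer(n + phy$Nnode)
    edgeRowOf[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
    parent <- integer(n + phy$Nnode)
    parent[phy$edge[, 2]] <- phy$edge[, 1]
    path <- phy$edge[e, 1]
    while (path[1] != n + 1L) path <- c(parent[path[1]], path)
    A <- lapply(seq_len(ncat), function(ci) matrix(engine$freqs, engine$k,
                                                   ncol(engine$codes)))
    scA <- lapply(seq_len(ncat), function(ci) numeric(ncol(engine$codes)))
    for (step in seq_along(path)) {
      p <- path[step]
      excl <- if (step < length(path)) path[step + 1L] else phy$edge[e, 2]
      for (ci in seq_len(ncat)) {
        O <- A[[ci]]; scO <- scA[[ci]]
        for (c2 in kids[[p]]) if (c2 != excl) {
          mm <- .childMessage(phy, engine, edgeLen, engine$rates[ci],
                              edgeRowOf[c2], down[[ci]])
          O <- O * mm$M
          scO <- scO + mm$sc
        }
        if (step < length(path)) {
          e2 <- edgeRowOf[excl]
          P <- .pmat(engine$eig, edgeLen[e2] * engine$rates[ci])
          Anew <- crossprod(P, O)
          s <- .rowMax(Anew); s[s == 0] <- 1
          A[[ci]] <- Anew / rep(s, each = engine$k)
          scA[[ci]] <- scO + log(s)
        } else { A[[ci]] <- O; scA[[ci]] <- scO }
      }
    }
    cats <- lapply(seq_len(ncat), function(ci) {
      cd <- .childD(phy, engine, e, down[[ci]])
      list(O = A[[ci]], scO = scA[[ci]], D = cd$D, scD = cd$sc,
           rate = engine$rates[ci], weight = engine$weights[ci])
    })
    opt <- .optimizeEdge1(list(list(cats = cats, eig = engine$eig,
                                    patWeights = engine$patWeights)),
                          NULL, .BRLEN_BOUNDS, 1e-5, edgeLen[e])
    edgeLens[[i]][e] <- opt$t
  }
  list(edgeLens = edgeLens,
       logLik = .totalLnL(phy, engines, edgeLens))
}

.searchLoop <- function(state, aln, config) {
  topEval <- 5L
  for (round in seq_len(config@maxNniRounds)) {
    nb <- nniNeighbors(state$phy)
    if (length(config@constraints))
      nb <- Filter(function(t2) .satisfiesConstraints(t2, config@constraints),
                   nb)
    if (!length(nb)) break
    # neighbors were enumerated on a reordered copy; re-map lengths
    base <- ape::reorder.phylo(state$phy, "cladewise")
    remap <- match(paste(base$edge[, 1], base$edge[, 2]),
                   paste(state$phy$edge[, 1], state$phy$edge[, 2]))
    lens0 <- lapply(state$edgeLens, function(el) el[remap])
    quick <- vapply(nb, function(t2)
      .quickEval(t2, state$engines, .swapEdgeLens(lens0, base, t2)),
      numeric(1))
    ord <- order(quick, decreasing = TRUE)
    best <- NULL
    for (j in head(ord, topEval)) {
      t2 <- nb[[j]]
      el2 <- .swapEdgeLens(lens0, base, t2)
      ce <- which(base$edge[, 2] != t2$edge[, 2])[1]  # a swapped edge row
      r <- .optimizeCentralEdge(t2, state$engines, el2, ce)
      if (is.null(best) || r$logLik > best$logLik)
        best <- list(phy = t2, edgeLens = r$edgeLens, logLik = r$logLik)
    }
    if (is.null(best) || best$logLik - state$logLik <= config@tol) break
    st2 <- .fitTopology(best$phy, aln, state$models, engines = state$engines,
                        edgeLens = best$edgeLens, tol = config@tol,
                        optimizeModel = config@optimizeModel, maxRounds = 2L)
    if (st2$logLik <= state$logLik + config@tol) break
    state <- st2
  }
  state
}

#' Maximum-likelihood tree search by NNI hill climbing
#'
#' Starts from a neighbor-joining (or user) tree, fits branch lengths and
#' model parameters, then repeats best-improvement NNI: all neighbors are
#' scored with carried branch lengths, the most promising are re-scored
#' after re-optimizing the rearranged branch, and an accepted move is
#' followed by full re-optimization.  Terminates when no neighbor improves
#' the log-likelihood by more than \code{config@tol}.  Deterministic given
#' the data and configuration; ties break to the first-enumerated
#' neighbor.
#'
#' @param aln the partitioned alignment (>= 4 taxa).
#' @param models per-partition models (see
#'   \code{\link{optimizeBranchLengths}}).
#' @param config a \code{\link{searchConfig}}.
#' @return a \code{PartitionedModelFit} whose log-likelihood is >= that of
#'   the starting tree.
#' @export
mlSearch <- function(aln, models = NULL, config = searchConfig()) {
  .assert(nrow(aln@seqs) >= 4L, "need >= 4 taxa")
  models <- .resolveModels(aln, models)
  phy0 <- if (config@startTree == "user") {
    .assert(!is.null(config@userTree), "userTree required")
    config@userTree
  } else if (length(config@constraints)) {
    .constrainedStartTree(aln, config@constraints)
  } else buildStartTree(aln)
  phy0 <- ape::multi2di(.unrootedBinary(phy0), random = FALSE)
  if (is.null(phy0$edge.length)) phy0$edge.length <- rep(0.1, nrow(phy0$edge))
  if (length(config@constraints))
    .assert(.satisfiesConstraints(phy0, config@constraints),
            "start tree violates constraints")
  state <- .fitTopology(phy0, aln, models, tol = config@tol,
                        optimizeModel = config@optimizeModel)
  state <- .searchLoop(state, aln, config)
  .asFit(state, aln, seed = config@seed)
}

#' Constrained maximum-likelihood search
#'
#' As \code{\link{mlSearch}} but every listed taxon group is forced to be
#' monophyletic: the starting tree assembles each group as a subtree and
#' NNI moves that would break any constrained group are rejected.
#'
#' @param aln the partitioned alignment.
#' @param models per-partition models.
#' @param constraints list of character vectors of taxon labels (disjoint
#'   or nested).
#' @param config a \code{\link{searchConfig}} (its constraints slot is
#'   replaced).
#' @return a \code{PartitionedModelFit} satisfying all constraints.
#' @export
constrainedMlSearch <- function(aln, models = NULL, constraints,
                                config = searchConfig()) {
  .checkConstraintSet(constraints, rownames(aln@seqs))
  config@constraints <- constraints
  config@startTree <- "nj"
  fit <- mlSearch(aln, models, config)
  .assert(.satisfiesConstraints(fit@tree, constraints),
          "internal error: constrained search violated constraints")
  fit
}

.checkConstraintSet <- function(constraints, taxa) {
  for (g in constraints) {
    .assert(all(g %in% taxa), paste("constraint taxon not in alignment:",
                                    paste(setdiff(g, taxa), collapse = ", ")))
  }
  for (i in seq_along(constraints)) for (j in seq_along(constraints)) {
    if (i >= j) next
    a <- constraints[[i]]; b <- constraints[[j]]
    ov <- length(intersect(a, b))
    if (ov > 0 && ov < min(length(a), length(b)) ||
        (ov > 0 && !(all(a %in% b) || all(b %in% a))))
      stop("constraints overlap without nesting", call. = FALSE)
  }
  invisible(TRUE)
}

# Start tree honouring (possibly nested) monophyly constraints: NJ among
# collapsed group super-taxa (average linkage), groups expanded
# recursively.
.constrainedStartTree <- function(aln, constraints) {
  D <- .pairwiseDistances(aln)
  taxa <- rownames(D)
  # maximal constraint groups within a taxon set
  topGroups <- function(set, cons) {
    cons <- lapply(cons, function(g) intersect(g, set))
    cons <- Filter(function(g) length(g) > 1 && length(g) < length(set), cons)
    keep <- rep(TRUE, length(cons))
    for (i in seq_along(cons)) for (j in seq_along(cons))
      if (i != j && keep[i] && all(cons[[i]] %in% cons[[j]]) &&
          length(cons[[j]]) > length(cons[[i]])) keep[i] <- FALSE
    cons[keep]
  }
  newickFor <- function(set, cons) {
    tg <- topGroups(set, cons)
    grouped <- unlist(tg)
    units <- c(lapply(tg, identity), as.list(setdiff(set, grouped)))
    labels <- vapply(units, function(u) paste(sort(unlist(u)), collapse = ""),
                     character(1))
    subNwk <- vapply(units, function(u) {
      u <- unlist(u)
      if (length(u) == 1L) u else newickFor(u, cons)
    }, character(1))
    if (length(units) == 1L) return(subNwk[1])
    if (length(units) == 2L)
      return(paste0("(", subNwk[1], ",", subNwk[2], ")"))
    Du <- matrix(0, length(units), length(units))
    for (i in seq_along(units)) for (j in seq_along(units)) if (i < j) {
      Du[i, j] <- Du[j, i] <- mean(D[unlist(units[[i]]), unlist(units[[j]])])
    }
    toks <- sprintf("zqx%dxqz", seq_along(units))
    dimnames(Du) <- list(toks, toks)
    tu <- if (length(units) == 3L)
      parseNewick(sprintf("(%s,%s,%s);", toks[1], toks[2], toks[3]))
    else ape::nj(Du)
    nwk <- writeNewick(ape::unroot(tu), digits = 1)
    nwk <- sub(";$", "", gsub(":[0-9.eE+-]+", "", nwk))
    for (i in seq_along(units))
      nwk <- sub(toks[i], subNwk[i], nwk, fixed = TRUE)
    nwk
  }
  nwk <- paste0(newickFor(taxa, constraints), ";")
  phy <- parseNewick(nwk)
  phy$edge.length <- rep(0.1, nrow(phy$edge))
  ape::multi2di(.unrootedBinary(phy), random = FALSE)
}
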