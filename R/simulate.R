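## Sequence simulation along rooted trees, including the study scenario:
## six labeled ingroup clades, one of them fast-evolving, and an outgroup
## attached by a (possibly long) stem -- the regime in which outgroup
## rooting is prone to long-branch attraction.

#' Simulate an alignment along a rooted tree
#'
#' Markov simulation: per site a gamma category is drawn (shared across
#' the whole tree, standard site-rate semantics), the root state is drawn
#' from the stationary frequencies, and states propagate along each branch
#' with probability matrices P(branch length x category rate x partition
#' rate).  Optionally a per-cell missingness mask replaces characters by
#' "-".
#'
#' @param tree rooted \code{ape::phylo} with branch lengths.
#' @param model a \code{RateModel}.
#' @param nSites number of sites.
#' @param rate partition-level rate multiplier (> 0).
#' @param seed RNG seed.
#' @param missingProb per-cell probability of replacing a character by a
#'   gap (default 0: gap-free alignments).
#' @return a single-partition \code{PartitionedAlignment} over the tree's
#'   tips.
#' @export
simulateAlignment <- function(tree, model, nSites, rate = 1, seed = NULL,
                              missingProb = 0) {
  .assert(rate > 0, "rate must be > 0")
  .assert(nSites >= 1, "nSites must be >= 1")
  states <- model@states
  k <- length(states)
  rw <- .modelRatesWeights(model)
  Q <- buildRateMatrix(model@exch, model@freqs)
  eig <- .eigenRateMatrix(Q, model@freqs)
  n <- length(tree$tip.label)
  .withSeed(seed, {
    cat <- sample.int(length(rw$rates), nSites, replace = TRUE,
                      prob = rw$weights)
    nodeState <- matrix(NA_integer_, n + tree$Nnode, nSites)
    nodeState[n + 1L, ] <- sample.int(k, nSites, replace = TRUE,
                                      prob = model@freqs)
    eo <- ape::reorder.phylo(tree, "cladewise")
    ord <- match(paste(eo$edge[, 1], eo$edge[, 2]),
                 paste(tree$edge[, 1], tree$edge[, 2]))
    for (i in seq_len(nrow(eo$edge))) {
      e <- ord[i]
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      t <- tree$edge.length[e] * rate
      for (ci in unique(cat)) {
        sel <- which(cat == ci)
        P <- .pmat(eig, t * rw$rates[ci])
        cum <- t(apply(P, 1L, cumsum))
        u <- runif(length(sel))
        nodeState[ch, sel] <- rowSums(u > cum[nodeState[p, sel], ,
                                              drop = FALSE]) + 1L
      }
    }
    m <- matrix(states[nodeState[seq_len(n), , drop = FALSE]], nrow = n,
                dimnames = list(tree$tip.label, NULL))
    if (missingProb > 0)
      m[matrix(runif(length(m)) < missingProb, nrow = n)] <- "-"
    partitionedAlignment(m, alphabet = model@alphabet)
  })
}

#' Simulate a partitioned alignment on a shared topology
#'
#' Partitions are simulated independently along the same tree with their
#' own models and rate multipliers, then concatenated.
#'
#' @param tree rooted tree with branch lengths.
#' @param models list of \code{RateModel}, one per partition.
#' @param widths integer vector of partition widths.
#' @param multipliers per-partition rate multipliers (default all 1).
#' @param seed RNG seed.
#' @param names partition names.
#' @param missingProb per-cell gap probability.
#' @return a \code{PartitionedAlignment}.
#' @export
simulatePartitioned <- function(tree, models, widths,
                                multipliers = rep(1, length(widths)),
                                seed = NULL,
                                names = paste0("part", seq_along(widths)),
                                missingProb = 0) {
  .assert(length(models) == length(widths), "one model per width")
  parts <- .withSeed(seed, lapply(seq_along(widths), function(i)
    simulateAlignment(tree, models[[i]], widths[i], rate = multipliers[i],
                      seed = NULL, missingProb = missingProb)))
  names(parts) <- names
  concatenatePartitions(parts)
}

#' Scenario parameters for the six-clade rooting study design
#'
#' @param groupSizes named integer vector: taxa per labeled ingroup group
#'   (default six groups of 4).
#' @param fastGroup name of the fast-evolving group.
#' @param fastMultiplier rate multiplier applied to every branch inside
#'   (and the stem of) the fast group; 1 = easy regime, about 3 = the
#'   long-branch artifact regime.
#' @param outgroupSize number of outgroup taxa.
#' @param stemLength outgroup stem branch length (0.5 = moderate; >= 1.5 =
#'   the long-stem artifact regime).
#' @param internalScale,terminalScale branch-length scales (substitutions
#'   per site) for ingroup internal and terminal branches.
#' @param widths partition widths.
#' @param models per-partition model tags.
#' @return a parameter list consumed by \code{\link{parabasaliaScenario}}.
#' @export
scenarioParams <- function(groupSizes = c(C = 4L, S = 4L, Tn = 4L, Tt = 4L,
                                          H = 4L, Tm = 4L),
                           fastGroup = "Tn", fastMultiplier = 1,
                           outgroupSize = 3L, stemLength = 0.5,
                           internalScale = 0.12, terminalScale = 0.10,
                           widths = c(prot = 1500L),
                           models = c("WAG+G4")) {
  .assert(all(groupSizes >= 1L), "group sizes must be >= 1")
  .assert(fastMultiplier >= 1, "fastMultiplier must be >= 1")
  .assert(fastGroup %in% names(groupSizes), "unknown fast group")
  list(groupSizes = groupSizes, fastGroup = fastGroup,
       fastMultiplier = fastMultiplier, outgroupSize = as.integer(outgroupSize),
       stemLength = stemLength, internalScale = internalScale,
       terminalScale = terminalScale, widths = widths, models = models)
}

# random rooted subtree for a group: coalescent-style topology with
# branch lengths ~ Uniform scaled by the terminal/internal scales
.randomGroupTree <- function(labels, internalScale, terminalScale) {
  n <- length(labels)
  if (n == 1L) return(.singleTipTree(labels, terminalScale))
  phy <- ape::rtree(n, rooted = TRUE, tip.label = labels, br = NULL)
  nb <- nrow(phy$edge)
  term <- phy$edge[, 2] <= n
  len <- numeric(nb)
  len[term] <- runif(sum(term), 0.5, 1.5) * terminalScale
  len[!term] <- runif(sum(!term), 0.5, 1.5) * internalScale
  phy$edge.length <- len
  phy
}

#' The six-clade rooting scenario generator
#'
#' Builds the study design: a rooted ingroup of six labeled clades on the
#' fixed backbone ((A, B), ((C, D), (E, F))) -- the true root is the
#' branch separating the first two groups from the other four -- with
#' randomized within-group topologies, a designated fast-evolving group
#' whose branch lengths are multiplied, and an outgroup clade attached at
#' the root by a stem branch.  The first two names of \code{groupSizes}
#' form the root-adjacent pair, so with the defaults the true root id is
#' "C+S" under \code{\link{classifyRootPosition}}'s labeling.
#'
#' @param params a \code{\link{scenarioParams}} list.
#' @param seed RNG seed.
#' @return list: \code{tree} (rooted, outgroup included), \code{groups}
#'   (named list of ingroup taxa), \code{outgroupTaxa},
#'   \code{trueRootId}, \code{ingroupTaxa}, \code{params}.
#' @export
parabasaliaScenario <- function(params = scenarioParams(), seed = 1) {
  gs <- params$groupSizes
  .assert(length(gs) == 6L, "the scenario uses six labeled groups")
  .withSeed(seed, {
    gnames <- names(gs)
    groups <- lapply(gnames, function(g)
      sprintf("%s_t%02d", g, seq_len(gs[[g]])))
    names(groups) <- gnames
    subs <- lapply(gnames, function(g) {
      mult <- if (g == params$fastGroup) params$fastMultiplier else 1
      t2 <- .randomGroupTree(groups[[g]], params$internalScale * mult,
                             params$terminalScale * mult)
      t2$root.edge <- runif(1, 0.5, 1.5) * params$internalScale * mult
      t2
    })
    names(subs) <- gnames
    nwk <- function(t2) sub(";$", "", writeNewick(t2, digits = 6))
    stemmed <- vapply(gnames, function(g)
      paste0(nwk(subs[[g]]), ":",
             formatC(subs[[g]]$root.edge, format = "f", digits = 6)),
      character(1))
    iS <- params$internalScale
    backbone <- sprintf("((%s,%s):%f,((%s,%s):%f,(%s,%s):%f):%f)",
                        stemmed[1], stemmed[2], iS,
                        stemmed[3], stemmed[4], iS,
                        stemmed[5], stemmed[6], iS, iS)
    og <- sprintf("OG_t%02d", seq_len(params$outgroupSize))
    ogTree <- .randomGroupTree(og, params$internalScale,
                               params$terminalScale)
    full <- sprintf("(%s:%f,%s:%f);", backbone, 0.05, nwk(ogTree),
                    params$stemLength)
    tree <- parseNewick(full)
    list(tree = tree, groups = groups, outgroupTaxa = og,
         trueRootId = paste(sort(gnames[1:2]), collapse = "+"),
         ingroupTaxa = unlist(groups, use.names = FALSE), params = params)
  })
}

#' Simulate the supermatrix for a scenario
#'
#' @param scenario output of \code{\link{parabasaliaScenario}}.
#' @param seed RNG seed.
#' @param missingProb per-cell gap probability.
#' @return a \code{PartitionedAlignment} over ingroup plus outgroup taxa.
#' @export
simulateScenarioAlignment <- function(scenario, seed = 1, missingProb = 0) {
  p <- scenario$params
  models <- lapply(p$models, modelFromTag)
  if (length(models) == 1L && length(p$widths) > 1L)
    models <- rep(models, length(p$widths))
  simulatePartitioned(scenario$tree, models, p$widths, seed = seed,
                      names = if (!is.null(names(p$widths)) &&
                                  all(nzchar(names(p$widths))))
                        names(p$widths) else paste0("part",
                                                    seq_along(p$widths)),
                      missingProb = missingProb)
}
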