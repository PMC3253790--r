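## Root-position analysis: enumerate candidate attachment branches on a
## fixed ingroup topology, graft the outgroup onto each, optimize, and
## compare the candidates with SH/AU tests; plus the stepwise long-branch
## outgroup removal series and constrained class-pairing tests.

#' Enumerate candidate root attachment branches
#'
#' Every branch of the unrooted ingroup topology is a candidate root
#' position (2n - 3 for a binary tree), identified by its ingroup
#' bipartition.  An optional named subset restricts (and labels) the
#' candidates, reproducing a hand-picked selection such as a set of
#' lettered positions on a published tree figure.
#'
#' @param ingroupTree unrooted ingroup topology (>= 3 taxa).
#' @param subset optional named list: candidate id -> character vector of
#'   taxa forming one side of the attachment bipartition.
#' @param groups optional named list of taxon groups used to derive
#'   human-readable ids (see \code{\link{classifyRootPosition}}).
#' @return data.frame: \code{id}, \code{edge} (edge row in
#'   \code{ingroupTree}), \code{split} (smaller side, ","-collapsed).
#' @export
enumerateRootAttachments <- function(ingroupTree, subset = NULL,
                                     groups = NULL) {
  phy <- .unrootedBinary(ingroupTree)
  .assert(length(phy$tip.label) >= 3L, "need >= 3 ingroup taxa")
  sets <- .edgeTipSets(phy)
  keys <- vapply(sets, .bipartKey, character(1), allTaxa = phy$tip.label)
  keep <- !duplicated(keys)
  edges <- which(keep)
  if (!is.null(subset)) {
    want <- vapply(subset, .bipartKey, character(1),
                   allTaxa = phy$tip.label)
    miss <- names(subset)[!want %in% keys[edges]]
    if (length(miss))
      stop("subset branch(es) not present in the ingroup tree: ",
           paste(miss, collapse = ", "), call. = FALSE)
    edges <- edges[match(want, keys[edges])]
    ids <- names(subset)
  } else if (!is.null(groups)) {
    ids <- vapply(edges, function(e)
      .rootIdFromSplit(sets[[e]], setdiff(phy$tip.label, sets[[e]]), groups),
      character(1))
    ids <- make.unique(ids, sep = "#")
  } else ids <- paste0("e", seq_along(edges))
  split <- vapply(edges, function(e) {
    s <- sets[[e]]
    if (length(s) > length(phy$tip.label) / 2)
      s <- setdiff(phy$tip.label, s)
    paste(sort(s), collapse = ",")
  }, character(1))
  data.frame(id = ids, edge = edges, split = split, stringsAsFactors = FALSE)
}

# single-tip phylo for grafting a lone outgroup taxon
.singleTipTree <- function(label, len = 0.1) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label,
                 edge.length = len, Nnode = 1L), class = "phylo")
}

#' Graft an outgroup subtree onto an ingroup branch
#'
#' The chosen branch is split at its midpoint by a new node and the
#' outgroup subtree is attached there by a stem of the given initial
#' length (re-optimized downstream).
#'
#' @param ingroupTree unrooted ingroup topology with branch lengths.
#' @param edge edge row index in \code{ingroupTree} (as enumerated by
#'   \code{\link{enumerateRootAttachments}}).
#' @param outgroup a \code{phylo} subtree, or a character vector of labels
#'   (a single label, or several joined as a rake resolved later).
#' @param stemLength initial stem branch length (default 0.5).
#' @return the full unrooted tree over ingroup plus outgroup taxa.
#' @export
graftOutgroup <- function(ingroupTree, edge, outgroup, stemLength = 0.5) {
  phy <- ingroupTree
  if (is.character(outgroup)) {
    og <- if (length(outgroup) == 1L) .singleTipTree(outgroup)
    else ape::multi2di(parseNewick(
      paste0("(", paste(outgroup, collapse = ","), ");")), random = FALSE)
    if (is.null(og$edge.length)) og$edge.length <- rep(0.1, nrow(og$edge))
  } else og <- outgroup
  .assert(length(intersect(og$tip.label, phy$tip.label)) == 0L,
          "outgroup and ingroup leaf sets overlap")
  og$root.edge <- stemLength
  child <- phy$edge[edge, 2]
  pos <- phy$edge.length[edge] / 2
  full <- ape::bind.tree(phy, og, where = child, position = pos)
  .unrootedBinary(full)
}

# map an ingroup split to a root-position id using group labels
.rootIdFromSplit <- function(sideA, sideB, groups) {
  describe <- function(side) {
    gin <- names(groups)[vapply(groups, function(g) {
      g <- intersect(g, c(sideA, sideB))
      length(g) > 0 && all(g %in% side)
    }, logical(1))]
    covered <- setequal(side, intersect(unlist(groups[gin]),
                                        c(sideA, sideB)))
    list(groups = sort(gin), complete = covered)
  }
  a <- describe(sideA); b <- describe(sideB)
  if (a$complete && b$complete) {
    pick <- if (length(a$groups) != length(b$groups)) {
      if (length(a$groups) < length(b$groups)) a else b
    } else if (paste(a$groups, collapse = "+") <=
               paste(b$groups, collapse = "+")) a else b
    return(paste(pick$groups, collapse = "+"))
  }
  side <- if (length(sideA) <= length(sideB)) sideA else sideB
  paste0("split:", paste(sort(side), collapse = ","))
}

#' Classify where the outgroup attaches on the ingroup topology
#'
#' Removes the outgroup and reports the ingroup bipartition at whose
#' branch it attached, as a root-position id derived from the taxonomic
#' group labels: a side consisting of complete groups is named by them
#' (e.g. \code{"Tm+Tn"}); otherwise the id lists the smaller side's taxa.
#' A non-monophyletic outgroup is classified by the attachment of its
#' first taxon (remaining outgroup taxa dropped) and flagged.
#'
#' @param fullTree tree containing ingroup and outgroup taxa.
#' @param ingroupTaxa ingroup taxon labels.
#' @param groups named list: group name -> taxon labels.
#' @return list: \code{id}, \code{sideA}, \code{sideB}, \code{flagged}.
#' @export
classifyRootPosition <- function(fullTree, ingroupTaxa, groups) {
  og <- setdiff(fullTree$tip.label, ingroupTaxa)
  .assert(length(og) >= 1L, "no outgroup taxon in tree")
  ing <- intersect(fullTree$tip.label, ingroupTaxa)
  flagged <- FALSE
  phy <- .unrootedBinary(fullTree)
  if (length(og) > 1L && !isMonophyletic(phy, og)) {
    flagged <- TRUE
    phy <- ape::drop.tip(phy, og[-1L])
    og <- og[1L]
  }
  rooted <- ape::root(phy, outgroup = og, resolve.root = TRUE)
  n <- length(rooted$tip.label)
  kids <- .phyloChildren(rooted)
  root <- n + 1L
  below <- .edgeTipSets(rooted)
  tipsBelow <- function(node) {
    e <- which(rooted$edge[, 2] == node)
    if (length(e)) below[[e]] else rooted$tip.label[node]
  }
  ingChild <- kids[[root]][!vapply(kids[[root]], function(ch)
    any(tipsBelow(ch) %in% og), logical(1))]
  # the ingroup side below the root splits into the attachment bipartition
  if (length(ingChild) == 1L && ingChild > n) {
    sides <- lapply(kids[[ingChild]], tipsBelow)
  } else {
    sides <- lapply(ingChild, tipsBelow)
  }
  if (length(sides) == 1L) sides <- c(sides, list(character(0)))
  sideA <- intersect(unlist(sides[1]), ing)
  sideB <- setdiff(ing, sideA)
  id <- .rootIdFromSplit(sideA, sideB, groups)
  list(id = id, sideA = sideA, sideB = sideB, flagged = flagged)
}

#' Root-position scan by outgroup grafting
#'
#' With the ingroup topology held fixed, the outgroup is grafted onto each
#' candidate branch, branch lengths (and optionally model parameters) are
#' re-optimized, per-site log-likelihoods collected, and all candidates
#' compared jointly with SH and AU tests.
#'
#' @param ingroupTree fixed unrooted ingroup topology (branch lengths used
#'   as starting values).
#' @param aln partitioned alignment containing ingroup AND outgroup taxa.
#' @param models per-partition models.
#' @param outgroupTaxa outgroup taxon labels present in \code{aln}.
#' @param candidates optional candidate table from
#'   \code{\link{enumerateRootAttachments}} (default: all branches).
#' @param groups optional group labels for candidate ids.
#' @param outgroupTree optional fixed internal topology for the outgroup;
#'   default: neighbor-joining arrangement of the outgroup taxa, kept
#'   fixed during grafting.
#' @param stemLength initial stem length before optimization.
#' @param tol optimization tolerance per candidate (default 1e-2;
#'   candidates only need comparable likelihoods).
#' @param optimizeModel re-optimize model parameters per candidate.
#' @param reSearch run a constrained NNI search per candidate (the
#'   attachment bipartition and the outgroup held monophyletic) instead of
#'   keeping the ingroup topology fixed.
#' @param Bsh,Bau,scales,seed resampling settings for the tests.
#' @return a \code{RootScanResult}.
#' @export
rootScan <- function(ingroupTree, aln, models = NULL, outgroupTaxa,
                     candidates = NULL, groups = NULL, outgroupTree = NULL,
                     stemLength = 0.5, tol = 1e-2, optimizeModel = FALSE,
                     reSearch = FALSE, Bsh = 10000, Bau = 10000,
                     scales = seq(0.5, 1.4, by = 0.1), seed = 1) {
  .assert(all(outgroupTaxa %in% rownames(aln@seqs)),
          "outgroup taxa missing from alignment")
  ingroupTree <- .unrootedBinary(ingroupTree)
  if (is.null(candidates))
    candidates <- enumerateRootAttachments(ingroupTree, groups = groups)
  models <- .resolveModels(aln, models)
  if (is.null(outgroupTree)) {
    outgroupTree <- if (length(outgroupTaxa) == 1L) outgroupTaxa
    else if (length(outgroupTaxa) == 2L)
      parseNewick(sprintf("(%s:0.1,%s:0.1);", outgroupTaxa[1],
                          outgroupTaxa[2]))
    else buildStartTree(dropTaxa(aln, setdiff(rownames(aln@seqs),
                                              outgroupTaxa)))
  }
  engines <- .buildEngines(aln, models)
  rows <- list(); sll <- list(); trees <- list()
  for (ci in seq_len(nrow(candidates))) {
    full <- graftOutgroup(ingroupTree, candidates$edge[ci], outgroupTree,
                          stemLength)
    st <- tryCatch({
      if (reSearch) {
        sideA <- strsplit(candidates$split[ci], ",", fixed = TRUE)[[1]]
        cons <- list(sideA, setdiff(ingroupTree$tip.label, sideA),
                     if (is.character(outgroupTree)) outgroupTree
                     else outgroupTree$tip.label)
        cons <- Filter(function(g) length(g) >= 2, cons)
        cfg <- searchConfig(startTree = "user", userTree = full, tol = tol,
                            constraints = cons,
                            optimizeModel = optimizeModel)
        fit <- mlSearch(aln, models, cfg)
        list(phy = fit@tree, edgeLens = fit@edgeLengths,
             models = fit@models, engines = .buildEngines(aln, fit@models),
             logLik = fit@logLik)
      } else {
        .fitTopology(full, aln, models, engines = engines, tol = tol,
                     optimizeModel = optimizeModel)
      }
    }, error = function(e) NULL)
    if (is.null(st)) {
      warning("candidate ", candidates$id[ci], " failed to optimize; skipped")
      next
    }
    sv <- numeric(nSites(aln))
    for (i in seq_along(st$engines))
      sv[.partitionSites(aln@partitions, i)] <-
        .partitionSiteLogLik(st$phy, st$engines[[i]], st$edgeLens[[i]])
    rows[[length(rows) + 1L]] <- candidates[ci, ]
    sll[[length(sll) + 1L]] <- sv
    trees[[length(trees) + 1L]] <- {
      t2 <- st$phy; t2$edge.length <- st$edgeLens[[1]]; t2
    }
  }
  .assert(length(rows) > 0L, "all candidates failed")
  cand <- do.call(rbind, rows)
  V <- do.call(rbind, sll)
  rownames(V) <- cand$id
  slm <- new("SiteLogLikelihoodMatrix", values = V,
             partitionIndex = .partitionIndex(aln))
  tt <- topologyTests(slm, Bsh = Bsh, Bau = Bau, scales = scales,
                      seed = seed)
  cand$logLik <- tt@table$logLik[match(cand$id, tt@table$id)]
  cand$deltaLnL <- tt@table$deltaLnL[match(cand$id, tt@table$id)]
  cand$pSH <- tt@table$pSH[match(cand$id, tt@table$id)]
  cand$pAU <- tt@table$pAU[match(cand$id, tt@table$id)]
  names(trees) <- cand$id
  new("RootScanResult", candidates = cand,
      bestId = cand$id[which.max(cand$logLik)],
      ingroupTree = ingroupTree,
      outgroupTaxa = as.character(outgroupTaxa), trees = trees)
}

#' Constrained pairing tests between taxonomic groups
#'
#' For every pair of groups whose union is NOT monophyletic in the
#' unconstrained ML tree, a constrained search forces the pair's union
#' (and each member group) to be monophyletic; the constrained trees are
#' then compared against the ML tree with SH and AU tests.  Pairs already
#' present in the ML tree are excluded, so g groups with m present pairs
#' yield choose(g, 2) - m rows.
#'
#' @param aln the partitioned alignment.
#' @param models per-partition models.
#' @param groups named list: group name -> taxon labels (disjoint).
#' @param mlFit optional unconstrained \code{PartitionedModelFit} (computed
#'   by \code{\link{mlSearch}} when NULL).
#' @param config search configuration for the constrained searches.
#' @param Bsh,Bau,scales,seed resampling settings.
#' @return list: \code{table} (one row per tested pairing: pair, logLik,
#'   deltaLnL, pSH, pAU), \code{mlFit}, \code{fits}.
#' @export
constraintPairTests <- function(aln, models = NULL, groups, mlFit = NULL,
                                config = searchConfig(tol = 1e-2),
                                Bsh = 10000, Bau = 10000,
                                scales = seq(0.5, 1.4, by = 0.1), seed = 1) {
  models <- .resolveModels(aln, models)
  if (is.null(mlFit)) mlFit <- mlSearch(aln, models, config)
  prs <- combn(sort(names(groups)), 2)
  keep <- !apply(prs, 2L, function(pr)
    isMonophyletic(mlFit@tree, c(groups[[pr[1]]], groups[[pr[2]]])))
  prs <- prs[, keep, drop = FALSE]
  rows <- list(); fits <- list()
  V <- matrix(mlFit@siteLogLik, nrow = 1,
              dimnames = list("ML", NULL))
  for (j in seq_len(ncol(prs))) {
    pr <- prs[, j]
    cons <- list(groups[[pr[1]]], groups[[pr[2]]],
                 c(groups[[pr[1]]], groups[[pr[2]]]))
    cons <- Filter(function(g) length(g) >= 2, cons)
    fit <- constrainedMlSearch(aln, models, cons, config)
    id <- paste(pr, collapse = "+")
    V <- rbind(V, fit@siteLogLik)
    rownames(V)[nrow(V)] <- id
    fits[[id]] <- fit
    rows[[id]] <- data.frame(pair = id, logLik = fit@logLik,
                             stringsAsFactors = FALSE)
  }
  slm <- new("SiteLogLikelihoodMatrix", values = V,
             partitionIndex = .partitionIndex(aln))
  tt <- topologyTests(slm, Bsh = Bsh, Bau = Bau, scales = scales,
                      seed = seed)
  tab <- do.call(rbind, rows)
  m <- match(tab$pair, tt@table$id)
  tab$deltaLnL <- tt@table$deltaLnL[m]
  tab$pSH <- tt@table$pSH[m]
  tab$pAU <- tt@table$pAU[m]
  rownames(tab) <- NULL
  list(table = tab, mlFit = mlFit, fits = fits)
}

#' Stepwise long-branch outgroup removal series
#'
#' Outgroup taxa are ranked by their terminal branch length in the full ML
#' tree (partition-width-weighted mean of per-partition optimized
#' lengths); at each step the longest-ranked are removed cumulatively and
#' the analysis (search + root classification) is repeated.
#'
#' @param aln partitioned alignment with ingroup and outgroup taxa.
#' @param models per-partition models.
#' @param outgroupTaxa outgroup labels.
#' @param schedule integer vector of cumulative removal counts (e.g.
#'   \code{c(2, 4)} removes the 2 longest, then the 4 longest); 0 steps
#'   mean the full analysis only.
#' @param groups group labels for root classification.
#' @param config search configuration.
#' @return data.frame: step, nRemoved, removed, rootId, logLik.
#' @export
longbranchRemovalSeries <- function(aln, models = NULL, outgroupTaxa,
                                    schedule = integer(0), groups,
                                    config = searchConfig(tol = 1e-2)) {
  .assert(length(outgroupTaxa) >= 2L, "need >= 2 outgroup taxa")
  .assert(all(schedule < length(outgroupTaxa)),
          "schedule would empty the outgroup")
  models <- .resolveModels(aln, models)
  ingroupTaxa <- setdiff(rownames(aln@seqs), outgroupTaxa)
  full <- mlSearch(aln, models, config)
  w <- with(full@partitions, end - start)
  n <- length(full@tree$tip.label)
  termLen <- vapply(outgroupTaxa, function(tx) {
    tip <- match(tx, full@tree$tip.label)
    e <- which(full@tree$edge[, 2] == tip)
    sum(w * vapply(full@edgeLengths, `[`, numeric(1), e)) / sum(w)
  }, numeric(1))
  ranked <- names(sort(termLen, decreasing = TRUE))
  steps <- c(0L, as.integer(schedule))
  out <- list()
  for (si in seq_along(steps)) {
    k <- steps[si]
    removed <- head(ranked, k)
    fit <- if (k == 0L) full
    else mlSearch(dropTaxa(aln, removed), models, config)
    cls <- classifyRootPosition(fit@tree, ingroupTaxa, groups)
    out[[si]] <- data.frame(step = si - 1L, nRemoved = k,
                            removed = paste(removed, collapse = ";"),
                            rootId = cls$id, logLik = fit@logLik,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
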