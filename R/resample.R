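## Nonparametric bootstrap, RELL resampling, SH and AU topology tests,
## and the chi-square composition-homogeneity test.
##
## All resampling draws sites with replacement independently WITHIN each
## partition, so every replicate preserves every partition's width (the
## natural convention for partitioned analyses; pooled resampling across
## partition boundaries is deliberately not offered).

# per-replicate site indices, drawn within partitions
.resampleIndices <- function(partitionIndex, scale = 1) {
  unlist(lapply(split(seq_along(partitionIndex), partitionIndex),
                function(sites) {
                  m <- max(1L, ceiling(scale * length(sites)))
                  sites[sample.int(length(sites), m, replace = TRUE)]
                }), use.names = FALSE)
}

#' Bootstrap-resample an alignment
#'
#' Sites are resampled with replacement independently within each
#' partition; each replicate therefore has exactly the original partition
#' widths.  Reproducible given the seed.
#'
#' @param aln a \code{PartitionedAlignment}.
#' @param B number of replicates (>= 1).
#' @param seed RNG seed.
#' @param indicesOnly return the list of site-index vectors instead of
#'   materialized alignments.
#' @return list of B \code{PartitionedAlignment}s (or index vectors).
#' @export
bootstrapResample <- function(aln, B, seed = 1, indicesOnly = FALSE) {
  .assert(B >= 1, "B must be >= 1")
  pidx <- .partitionIndex(aln)
  idx <- .withSeed(seed, lapply(seq_len(B),
                                function(b) .resampleIndices(pidx)))
  if (indicesOnly) return(idx)
  lapply(idx, function(ii)
    new("PartitionedAlignment", seqs = aln@seqs[, ii, drop = FALSE],
        partitions = aln@partitions))
}

#' Bootstrap support values on a reference tree
#'
#' Support of each non-trivial reference bipartition is 100 times the
#' fraction of replicate trees containing it; stored as internal node
#' labels of the returned tree.
#'
#' @param trees list of replicate trees (same leaf set).
#' @param refTree the reference topology.
#' @return \code{refTree} with node labels set to support percentages
#'   (root label empty).
#' @export
bootstrapSupport <- function(trees, refTree) {
  for (t2 in trees)
    .assert(setequal(t2$tip.label, refTree$tip.label), "leaf-set mismatch")
  refKeys <- .bipartitionKeys(refTree)
  counts <- setNames(numeric(length(refKeys)), refKeys)
  for (t2 in trees) {
    hit <- intersect(.bipartitionKeys(t2), refKeys)
    counts[hit] <- counts[hit] + 1
  }
  supp <- 100 * counts / length(trees)
  n <- length(refTree$tip.label)
  lab <- rep("", refTree$Nnode)
  for (j in seq_along(refKeys)) {
    e <- as.integer(names(refKeys)[j])
    lab[refTree$edge[e, 2] - n] <- formatC(supp[j], format = "fg")
  }
  refTree$node.label <- lab
  refTree
}

#' Bootstrap replicate trees
#'
#' Full tree searches on bootstrap-resampled alignments, with a cheaper
#' convergence tolerance (1e-2) than the main search for speed.
#'
#' @param aln the partitioned alignment.
#' @param models per-partition models.
#' @param B replicate count.
#' @param seed RNG seed.
#' @param config search configuration applied to each replicate.
#' @return list of B \code{phylo} trees.
#' @export
bootstrapTrees <- function(aln, models = NULL, B = 100, seed = 1,
                           config = searchConfig(tol = 1e-2)) {
  reps <- bootstrapResample(aln, B, seed)
  lapply(reps, function(a) mlSearch(a, models, config)@tree)
}

#' RELL replicate log-likelihood totals
#'
#' Resampling estimated log-likelihoods: per replicate, site columns are
#' resampled with replacement within partitions (same indices for all
#' topologies) and summed per topology; no re-optimization.
#'
#' @param sitelnl a \code{SiteLogLikelihoodMatrix} (or plain matrix, one
#'   partition assumed).
#' @param B replicate count.
#' @param seed RNG seed.
#' @param scale resample-size factor r (AU multiscale); each partition
#'   contributes ceiling(r * width) sites.
#' @return matrix topologies x B of replicate totals.
#' @export
rellReplicates <- function(sitelnl, B, seed = 1, scale = 1) {
  v <- if (is(sitelnl, "SiteLogLikelihoodMatrix")) sitelnl@values else sitelnl
  pidx <- if (is(sitelnl, "SiteLogLikelihoodMatrix")) sitelnl@partitionIndex
  else rep(1L, ncol(v))
  .withSeed(seed, {
    counts <- matrix(0L, ncol(v), B)
    for (b in seq_len(B)) {
      ii <- .resampleIndices(pidx, scale)
      counts[, b] <- tabulate(ii, nbins = ncol(v))
    }
    v %*% counts
  })
}

#' Shimodaira-Hasegawa topology test
#'
#' Standard SH construction on RELL replicates: replicate totals are
#' centered per topology (subtracting that topology's replicate mean); for
#' each replicate the centered maximum over topologies is taken, and the
#' p-value of topology i is the proportion of replicates in which
#' (centered max - centered value of i) exceeds the observed
#' log-likelihood deficit of i.  The best topology has p = 1 by
#' construction; the test is conservative.
#'
#' @param sitelnl \code{SiteLogLikelihoodMatrix} (>= 2 topologies; a
#'   single topology yields p = 1 with a warning).
#' @param B RELL replicates (default 10000).
#' @param seed RNG seed.
#' @return a \code{TopologyTestResult} with the \code{pSH} column filled.
#' @export
shTest <- function(sitelnl, B = 10000, seed = 1) {
  v <- sitelnl@values
  obs <- rowSums(v)
  delta <- max(obs) - obs
  if (nrow(v) < 2L) {
    warning("single topology: SH p-value is 1 trivially")
    p <- 1
  } else {
    R <- rellReplicates(sitelnl, B, seed)
    Rc <- R - rowMeans(R)
    mx <- apply(Rc, 2L, max)
    p <- vapply(seq_len(nrow(v)), function(i)
      mean((mx - Rc[i, ]) >= delta[i]), numeric(1))
  }
  tab <- data.frame(id = rownames(v), logLik = obs, deltaLnL = delta,
                    pSH = p, stringsAsFactors = FALSE)
  new("TopologyTestResult", table = tab, B = as.integer(B),
      scales = numeric(0), seed = seed)
}

#' Approximately unbiased topology test
#'
#' Multiscale bootstrap: at each scale r the sites are RELL-resampled to
#' ceiling(r * width) per partition and the bootstrap proportion of
#' replicates in which each topology attains the maximum is recorded.
#' Proportions are clipped to [1/(B+1), 1 - 1/(B+1)], transformed to
#' z-values, and fitted by weighted least squares to
#' z(r) = d * sqrt(r) + c / sqrt(r) with weights from the binomial
#' variance; p_AU = 1 - Phi(d - c).  Degenerate cases (a topology winning
#' or losing every replicate at every scale) are flagged and given p = 1
#' or p = 0.
#'
#' @param sitelnl \code{SiteLogLikelihoodMatrix} (>= 2 topologies).
#' @param scales resample-size factors (default 0.5 ... 1.4).
#' @param B replicates per scale (default 10000).
#' @param seed RNG seed.
#' @return a \code{TopologyTestResult} with \code{pAU} (and \code{pSH} via
#'   a companion SH run at scale 1 omitted; run \code{\link{shTest}} for
#'   SH p-values).
#' @export
auTest <- function(sitelnl, scales = seq(0.5, 1.4, by = 0.1), B = 10000,
                   seed = 1) {
  v <- sitelnl@values
  .assert(nrow(v) >= 2L, "AU test needs >= 2 topologies")
  ntop <- nrow(v)
  bp <- matrix(NA_real_, ntop, length(scales))
  for (si in seq_along(scales)) {
    R <- rellReplicates(sitelnl, B, seed = seed + 7919L * si,
                        scale = scales[si])
    # exact ties (e.g. duplicated topologies) are broken at random so
    # that exchangeable candidates share the wins symmetrically
    win <- .withSeed(seed + 104729L * si,
                     max.col(t(R), ties.method = "random"))
    bp[, si] <- tabulate(win, nbins = ntop) / B
  }
  clip <- function(x) pmin(pmax(x, 1 / (B + 1)), 1 - 1 / (B + 1))
  pAU <- numeric(ntop)
  flag <- character(ntop)
  for (i in seq_len(ntop)) {
    # a topology winning (or losing) essentially every replicate at every
    # scale leaves no information for the z(r) fit: the clipped, flat
    # z-curve would yield d - c ~ 0 and a spurious p ~ 0.5
    interior <- bp[i, ] > 1 / (B + 1) & bp[i, ] < 1 - 1 / (B + 1)
    # a handful of wins (or losses) across all scales carries no slope
    # information for the z(r) fit, only binomial noise
    if (sum(bp[i, ]) * B < 10) { pAU[i] <- 0; flag[i] <- "degenerate-low"; next }
    if (sum(1 - bp[i, ]) * B < 10) { pAU[i] <- 1; flag[i] <- "degenerate-high"; next }
    if (sum(interior) < 2L) {
      if (mean(bp[i, ]) < 0.5) { pAU[i] <- 0; flag[i] <- "degenerate-low" }
      else { pAU[i] <- 1; flag[i] <- "degenerate-high" }
      next
    }
    # fit on the informative scales only: a scale whose proportion sits at
    # the clip bound carries a censored z-value that would flatten the
    # curve and bias d and c
    sel <- which(interior)
    bpc <- clip(bp[i, sel])
    z <- qnorm(1 - bpc)
    w <- B * dnorm(z)^2 / (bpc * (1 - bpc))
    X <- cbind(sqrt(scales[sel]), 1 / sqrt(scales[sel]))
    fit <- stats::lm.wfit(X, z, w)
    dc <- fit$coefficients
    pAU[i] <- 1 - pnorm(dc[1] - dc[2])
    flag[i] <- ""
  }
  obs <- rowSums(v)
  tab <- data.frame(id = rownames(v), logLik = obs,
                    deltaLnL = max(obs) - obs, pAU = pAU, auFlag = flag,
                    stringsAsFactors = FALSE)
  new("TopologyTestResult", table = tab, B = as.integer(B), scales = scales,
      seed = seed)
}

#' Joint SH and AU tests
#'
#' Convenience wrapper running both tests on the same site log-likelihood
#' matrix and merging the result tables.
#'
#' @inheritParams auTest
#' @param Bsh,Bau replicate counts for SH and AU.
#' @return a \code{TopologyTestResult} with \code{pSH} and \code{pAU}.
#' @export
topologyTests <- function(sitelnl, Bsh = 10000, Bau = 10000,
                          scales = seq(0.5, 1.4, by = 0.1), seed = 1) {
  sh <- shTest(sitelnl, B = Bsh, seed = seed)
  tab <- sh@table
  if (nrow(sitelnl@values) >= 2L) {
    au <- auTest(sitelnl, scales = scales, B = Bau, seed = seed)
    tab$pAU <- au@table$pAU[match(tab$id, au@table$id)]
    tab$auFlag <- au@table$auFlag[match(tab$id, au@table$id)]
  } else {
    tab$pAU <- 1
    tab$auFlag <- "single"
  }
  new("TopologyTestResult", table = tab, B = as.integer(max(Bsh, Bau)),
      scales = scales, seed = seed)
}

#' Chi-square composition-homogeneity test
#'
#' For each taxon, observed state counts (non-missing sites only) are
#' compared with expected counts given the overall all-taxa state
#' frequencies; the statistic is summed over states, df = states - 1, and
#' the p-value is the chi-square upper tail.  Run per partition.
#'
#' @param aln a \code{PartitionedAlignment}.
#' @param partition partition name or index (default: every partition).
#' @return data.frame: partition, taxon, statistic, df, p.
#' @export
compositionChisq <- function(aln, partition = NULL) {
  p <- aln@partitions
  sel <- if (is.null(partition)) seq_len(nrow(p))
  else if (is.character(partition)) match(partition, p$name)
  else as.integer(partition)
  out <- list()
  for (i in sel) {
    m <- .partitionMatrix(aln, i)
    states <- .alphabetStates(p$alphabet[i])
    codes <- matrix(match(toupper(m), states), nrow = nrow(m))
    overall <- tabulate(codes[!is.na(codes)], nbins = length(states))
    .assert(sum(overall) > 0, "partition has no observed characters")
    freq <- overall / sum(overall)
    for (tx in seq_len(nrow(m))) {
      obs <- tabulate(codes[tx, !is.na(codes[tx, ])], nbins = length(states))
      ntx <- sum(obs)
      if (ntx == 0L)
        stop("taxon with zero non-missing sites: ", rownames(m)[tx],
             call. = FALSE)
      expd <- freq * ntx
      ok <- expd > 0
      stat <- sum((obs[ok] - expd[ok])^2 / expd[ok])
      df <- length(states) - 1L
      out[[length(out) + 1L]] <- data.frame(
        partition = p$name[i], taxon = rownames(m)[tx], statistic = stat,
        df = df, p = pchisq(stat, df, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
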