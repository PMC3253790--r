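## Per-site log-likelihoods by Felsenstein pruning with per-node numerical
## rescaling, plus the brute-force enumeration oracle used to validate it.
##
## Conventions: gap/ambiguity characters are fully missing (tip partial of
## ones); gamma categories have equal weights; the root is weighted by the
## stationary frequencies, so for reversible models the value is invariant
## to the rooting point.  Site patterns are compressed with weights for
## speed; all exported values are on uncompressed per-site semantics.

# Precompute everything reusable across likelihood evaluations for one
# partition: eigendecomposition, category rates, compressed patterns.
.likEngine <- function(mat, model, taxa = rownames(mat)) {
  states <- model@states
  k <- length(states)
  codes <- matrix(match(toupper(mat), states), nrow = nrow(mat),
                  dimnames = dimnames(mat))
  pat <- apply(codes, 2L, paste, collapse = "\r")
  pat[colSums(!is.na(codes)) == 0L] <- "allmissing"
  uniq <- !duplicated(pat)
  siteToPat <- match(pat, pat[uniq])
  patCodes <- codes[, uniq, drop = FALSE]
  rw <- .modelRatesWeights(model)
  Q <- buildRateMatrix(model@exch, model@freqs)
  list(eig = .eigenRateMatrix(Q, model@freqs), freqs = model@freqs,
       k = k, rates = rw$rates, weights = rw$weights,
       codes = patCodes, siteToPat = siteToPat,
       patWeights = tabulate(siteToPat, nbins = sum(uniq)), taxa = taxa)
}

.rowMax <- function(m) {
  out <- m[1L, ]
  for (r in seq_len(nrow(m))[-1L]) out <- pmax(out, m[r, ])
  out
}

# Postorder "down" partials for one gamma category.
# Returns list(partial = list per node (k x npat), scaler = list per node).
.downPartials <- function(phy, engine, edgeLen, rate) {
  n <- length(phy$tip.label)
  eo <- ape::reorder.phylo(phy, "postorder")
  ord <- match(paste(eo$edge[, 1], eo$edge[, 2]),
               paste(phy$edge[, 1], phy$edge[, 2]))
  k <- engine$k
  npat <- ncol(engine$codes)
  tipRow <- match(phy$tip.label, engine$taxa)
  partial <- vector("list", n + phy$Nnode)
  scaler <- vector("list", n + phy$Nnode)
  Pm <- lapply(seq_len(nrow(phy$edge)),
               function(e) .pmat(engine$eig, edgeLen[e] * rate))
  for (i in seq_len(nrow(eo$edge))) {
    e <- ord[i]
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    P <- Pm[[e]]
    if (ch <= n) {
      cd <- engine$codes[tipRow[ch], ]
      M <- matrix(1, k, npat)
      obs <- which(!is.na(cd))
      M[, obs] <- P[, cd[obs]]
      sc <- NULL
    } else {
      pc <- partial[[ch]]
      s <- .rowMax(pc)
      s[s == 0] <- 1
      M <- P %*% (pc / rep(s, each = k))
      sc <- scaler[[ch]] + log(s)
    }
    if (is.null(partial[[p]])) {
      partial[[p]] <- M
      scaler[[p]] <- if (is.null(sc)) numeric(npat) else sc
    } else {
      partial[[p]] <- partial[[p]] * M
      if (!is.null(sc)) scaler[[p]] <- scaler[[p]] + sc
    }
  }
  list(partial = partial, scaler = scaler, Pm = Pm)
}

# Per-pattern log-likelihood for one partition (all categories combined).
.patternLogLik <- function(phy, engine, edgeLen) {
  root <- length(phy$tip.label) + 1L
  perCat <- matrix(NA_real_, length(engine$rates), ncol(engine$codes))
  for (ci in seq_along(engine$rates)) {
    dp <- .downPartials(phy, engine, edgeLen, engine$rates[ci])
    lik <- colSums(engine$freqs * dp$partial[[root]])
    perCat[ci, ] <- log(lik) + dp$scaler[[root]]
  }
  .colLogSumExp(perCat + log(engine$weights))
}

.partitionSiteLogLik <- function(phy, engine, edgeLen) {
  .patternLogLik(phy, engine, edgeLen)[engine$siteToPat]
}

#' Per-site log-likelihoods under a fixed tree and model
#'
#' Felsenstein pruning with per-node rescaling; gamma categories are
#' averaged with equal weights and the root is weighted by the stationary
#' frequencies.  An all-missing column has log-likelihood 0.
#'
#' @param tree \code{ape::phylo} with branch lengths; leaves must match the
#'   alignment's taxa.
#' @param aln a single-partition \code{PartitionedAlignment} (or character
#'   matrix).
#' @param model a \code{RateModel} matching the alignment's alphabet.
#' @return numeric vector of per-site log-likelihoods.
#' @export
siteLogLik <- function(tree, aln, model) {
  mat <- if (is(aln, "PartitionedAlignment")) aln@seqs else aln
  .assert(setequal(tree$tip.label, rownames(mat)),
          "tree leaves and alignment taxa differ")
  .assert(!is.null(tree$edge.length), "tree must have branch lengths")
  engine <- .likEngine(mat, model)
  .partitionSiteLogLik(tree, engine, tree$edge.length)
}

#' Total log-likelihood of a partitioned fit
#'
#' Sum over partitions of per-site log-likelihood sums, each partition
#' evaluated with its own model and branch lengths on the shared topology.
#'
#' @param fit a \code{PartitionedModelFit}.
#' @param aln the partitioned alignment the fit refers to.
#' @return total log-likelihood (numeric scalar); per-site vectors are in
#'   \code{fit@siteLogLik} after \code{\link{optimizeBranchLengths}}.
#' @export
totalPartitionedLogLik <- function(fit, aln) {
  p <- aln@partitions
  .assert(nrow(p) == length(fit@models), "partition count mismatch")
  tot <- 0
  for (i in seq_len(nrow(p))) {
    engine <- .likEngine(.partitionMatrix(aln, i), fit@models[[i]])
    tot <- tot + sum(.partitionSiteLogLik(fit@tree, engine,
                                          fit@edgeLengths[[i]]))
  }
  tot
}

#' Brute-force likelihood by enumeration over internal states
#'
#' Independent oracle for the pruning implementation: sums the joint
#' probability over every assignment of states to internal nodes, for
#' every gamma category.  Guarded to small instances.
#'
#' @param tree \code{ape::phylo} with branch lengths.
#' @param aln single-partition alignment or character matrix.
#' @param model a \code{RateModel}.
#' @return total log-likelihood.
#' @export
bruteForceLogLik <- function(tree, aln, model) {
  mat <- if (is(aln, "PartitionedAlignment")) aln@seqs else aln
  .assert(nrow(mat) <= 7L && ncol(mat) <= 30L,
          "instance too large for brute force (<= 7 taxa, <= 30 sites)")
  n <- length(tree$tip.label)
  k <- length(model@states)
  codes <- matrix(match(toupper(mat), model@states), nrow = nrow(mat),
                  dimnames = dimnames(mat))
  codes <- codes[tree$tip.label, , drop = FALSE]
  rw <- .modelRatesWeights(model)
  Q <- buildRateMatrix(model@exch, model@freqs)
  eig <- .eigenRateMatrix(Q, model@freqs)
  A <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  nA <- nrow(A)
  nodeCol <- function(v) A[, v - n]
  siteLik <- numeric(ncol(codes))
  for (ci in seq_along(rw$rates)) {
    Pm <- lapply(tree$edge.length,
                 function(t) .pmat(eig, t * rw$rates[ci]))
    base <- model@freqs[nodeCol(n + 1L)]
    intEdge <- which(tree$edge[, 2] > n)
    for (e in intEdge)
      base <- base * Pm[[e]][cbind(nodeCol(tree$edge[e, 1]),
                                   nodeCol(tree$edge[e, 2]))]
    tipEdge <- which(tree$edge[, 2] <= n)
    for (s in seq_len(ncol(codes))) {
      v <- base
      for (e in tipEdge) {
        cd <- codes[tree$edge[e, 2], s]
        if (!is.na(cd)) v <- v * Pm[[e]][cbind(nodeCol(tree$edge[e, 1]), cd)]
      }
      siteLik[s] <- siteLik[s] + rw$weights[ci] * sum(v)
    }
  }
  sum(log(siteLik))
}

#' Write per-site log-likelihoods in TREE-PUZZLE .sitelh dialect
#'
#' First line: number of trees and number of sites; then one row per tree,
#' the tree name followed by the per-site values (the format CONSEL-style
#' tools consume).
#'
#' @param x a \code{SiteLogLikelihoodMatrix} or plain matrix with rownames.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeSitelh <- function(x, path) {
  m <- if (is(x, "SiteLogLikelihoodMatrix")) x@values else x
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("  %d %d", nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(rownames(m)[i],
                     paste(formatC(m[i, ], format = "f", digits = 6),
                           collapse = " ")), con)
  invisible(path)
}

#' Read a .sitelh per-site log-likelihood file
#' @param path file in the dialect written by \code{\link{writeSitelh}}.
#' @param partitionIndex optional site-to-partition map (default: one
#'   partition).
#' @return a \code{SiteLogLikelihoodMatrix}.
#' @export
readSitelh <- function(path, partitionIndex = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  rows <- lapply(lines[-1][nzchar(trimws(lines[-1]))], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    list(id = f[1], v = as.numeric(f[-1]))
  })
  m <- do.call(rbind, lapply(rows, `[[`, "v"))
  rownames(m) <- vapply(rows, `[[`, character(1), "id")
  .assert(nrow(m) == hdr[1] && ncol(m) == hdr[2], "header/matrix mismatch")
  if (is.null(partitionIndex)) partitionIndex <- rep(1L, ncol(m))
  new("SiteLogLikelihoodMatrix", values = m,
      partitionIndex = as.integer(partitionIndex))
}
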