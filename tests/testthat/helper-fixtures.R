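# Shared fixtures: random models, trees and alignments built in code.

randomSimplex <- function(k) {
  x <- runif(k, 0.2, 1)
  x / sum(x)
}

randomGtr <- function(shape = NA) {
  gtrModel(rates = runif(6, 0.3, 3), freqs = randomSimplex(4),
           shape = if (is.na(shape)) exp(runif(1, log(0.3), log(2))) else shape,
           nCat = 4L)
}

randomWag <- function(shape = NA) {
  wagModel(shape = if (is.na(shape)) exp(runif(1, log(0.3), log(2)))
           else shape, nCat = 4L)
}

randomTreeWithLengths <- function(n, lo = 0.05, hi = 0.4) {
  ape::rtree(n, rooted = TRUE, br = function(k) runif(k, lo, hi))
}

# small random instance for oracle comparisons
randomInstance <- function(ntaxa, nsites, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  model <- if (alphabet == "nt") randomGtr() else randomWag()
  tree <- randomTreeWithLengths(ntaxa)
  aln <- simulateAlignment(tree, model, nsites)
  list(tree = tree, aln = aln, model = model)
}

# independent naive SH implementation (straight from the definition, no
# shared code with shTest beyond the RELL index draws being re-implemented)
naiveSH <- function(values, B, seed) {
  set.seed(seed)
  N <- ncol(values)
  obs <- rowSums(values)
  delta <- max(obs) - obs
  reps <- matrix(NA_real_, nrow(values), B)
  for (b in seq_len(B)) {
    idx <- sample.int(N, N, replace = TRUE)
    reps[, b] <- rowSums(values[, idx, drop = FALSE])
  }
  repsC <- reps - rowMeans(reps)
  mx <- apply(repsC, 2, max)
  vapply(seq_len(nrow(values)), function(i)
    mean((mx - repsC[i, ]) >= delta[i]), numeric(1))
}

# naive bipartition counter for bootstrap supports
naiveSupportCounts <- function(trees, refTree) {
  splitSet <- function(phy) {
    pp <- ape::prop.part(phy)
    labs <- attr(pp, "labels")
    keys <- vapply(pp, function(ix) {
      side <- sort(labs[ix])
      other <- sort(setdiff(labs, side))
      if (labs[order(labs)][1] %in% side)
        paste(other, collapse = "|") else paste(side, collapse = "|")
    }, character(1))
    unique(keys)
  }
  # prop.part works on rooted clades; unroot-invariant via the key scheme
  ref <- splitSet(ape::root(refTree, outgroup = sort(refTree$tip.label)[1],
                            resolve.root = TRUE))
  counts <- setNames(numeric(length(ref)), ref)
  for (t2 in trees) {
    s <- splitSet(ape::root(t2, outgroup = sort(t2$tip.label)[1],
                            resolve.root = TRUE))
    hit <- intersect(s, ref)
    counts[hit] <- counts[hit] + 1
  }
  counts
}
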