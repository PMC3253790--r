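## Bipartition machinery shared by search, bootstrap and root
## classification.  A bipartition is keyed by the sorted tip labels of the
## side NOT containing the reference taxon (the lexicographically smallest
## label of the full leaf set), collapsed with "|": a rooting-independent
## canonical key.

.bipartKey <- function(side, allTaxa) {
  ref <- min(allTaxa)
  if (ref %in% side) side <- setdiff(allTaxa, side)
  paste(sort(side, method = "radix"), collapse = "|")
}

# Tip-label sets below each edge's child node.
.edgeTipSets <- function(phy) {
  n <- length(phy$tip.label)
  eo <- ape::reorder.phylo(phy, "postorder")
  below <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) below[[i]] <- phy$tip.label[i]
  for (i in seq_len(nrow(eo$edge))) {
    p <- eo$edge[i, 1]; ch <- eo$edge[i, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  # return in the ORIGINAL edge order of phy
  lapply(phy$edge[, 2], function(ch) below[[ch]])
}

# Canonical keys for all non-trivial internal bipartitions of an
# (unrooted-interpreted) tree; named by edge row index.
.bipartitionKeys <- function(phy, trivial = FALSE) {
  n <- length(phy$tip.label)
  sets <- .edgeTipSets(phy)
  keys <- vapply(sets, .bipartKey, character(1), allTaxa = phy$tip.label)
  sz <- lengths(sets)
  keep <- rep(TRUE, length(keys))
  if (!trivial) keep <- sz > 1L & sz < n - 1L
  # the root edge of a rooted tree duplicates a key; drop duplicates
  keep <- keep & !duplicated(keys)
  setNames(keys[keep], which(keep))
}

#' Robinson-Foulds style bipartition comparison
#' @param t1,t2 trees (\code{ape::phylo}) on the same leaf set.
#' @return number of bipartitions present in exactly one tree.
#' @export
bipartitionDistance <- function(t1, t2) {
  .assert(setequal(t1$tip.label, t2$tip.label), "leaf sets differ")
  k1 <- .bipartitionKeys(t1); k2 <- .bipartitionKeys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Test monophyly of a taxon group in an unrooted tree
#' @param phy a tree.
#' @param group character vector of tip labels.
#' @return TRUE if some branch splits exactly \code{group} from the rest
#'   (trivial groups of size 1 or n-0/n-1 are monophyletic by convention).
#' @export
isMonophyletic <- function(phy, group) {
  group <- intersect(phy$tip.label, group)
  n <- length(phy$tip.label)
  if (length(group) <= 1L || length(group) >= n - 1L) return(TRUE)
  key <- .bipartKey(group, phy$tip.label)
  key %in% .bipartitionKeys(phy)
}

.satisfiesConstraints <- function(phy, constraints) {
  all(vapply(constraints, function(g) isMonophyletic(phy, g), logical(1)))
}

# Unrooted binary normalization: collapse a degree-2 root.
.unrootedBinary <- function(phy) {
  if (length(phy$tip.label) > 2L && ape::is.rooted(phy))
    phy <- ape::unroot(phy)
  phy
}
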