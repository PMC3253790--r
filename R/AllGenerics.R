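#' @name accessors
#' @title Accessors for rootgraft objects
#' @description Small accessor generics: taxon labels, alignment width,
#'   partition scheme, and the character matrix itself.
#' @param x an object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))
#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname accessors
#' @export
setGeneric("partitionScheme", function(x) standardGeneric("partitionScheme"))
#' @rdname accessors
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' @rdname accessors
#' @export
setMethod("taxonNames", "PartitionedAlignment", function(x) rownames(x@seqs))
#' @rdname accessors
#' @export
setMethod("nSites", "PartitionedAlignment", function(x) ncol(x@seqs))
#' @rdname accessors
#' @export
setMethod("partitionScheme", "PartitionedAlignment", function(x) x@partitions)
#' @rdname accessors
#' @export
setMethod("alignmentMatrix", "PartitionedAlignment", function(x) x@seqs)

#' @rdname accessors
#' @export
setMethod("taxonNames", "GeneSequenceSet", function(x) unique(unname(x@taxa)))

#' Total log-likelihood of a partitioned fit
#' @param object a \code{PartitionedModelFit}.
#' @param ... unused.
#' @return numeric scalar.
#' @export
setMethod("logLik", "PartitionedModelFit", function(object, ...) object@logLik)

setMethod("show", "PartitionedAlignment", function(object) {
  p <- object@partitions
  cat("PartitionedAlignment:", nrow(object@seqs), "taxa x",
      ncol(object@seqs), "sites,", nrow(p), "partition(s)\n")
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %s [%d,%d) %s %s\n", p$name[i], p$start[i], p$end[i],
                p$alphabet[i], p$model[i]))
})

setMethod("show", "GeneSequenceSet", function(object) {
  cat("GeneSequenceSet '", object@gene, "': ", length(object@sequences),
      " records, ", length(unique(object@taxa)), " taxa\n", sep = "")
})

setMethod("show", "RateModel", function(object) {
  cat("RateModel", object@name, "(", object@alphabet, ",",
      length(object@states), "states )\n")
  if (!is.na(object@gammaShape))
    cat("  gamma shape:", format(object@gammaShape, digits = 4),
        "with", object@nCat, "categories\n")
  if (object@pInv > 0) cat("  p-invariant:", object@pInv, "\n")
})

setMethod("show", "PartitionedModelFit", function(object) {
  cat("PartitionedModelFit:", length(object@models), "partition(s),",
      length(object@tree$tip.label), "taxa\n")
  cat("  log-likelihood:", format(object@logLik, digits = 10), "\n")
})

setMethod("show", "SiteLogLikelihoodMatrix", function(object) {
  cat("SiteLogLikelihoodMatrix:", nrow(object@values), "topologies x",
      ncol(object@values), "sites\n")
})

setMethod("show", "TopologyTestResult", function(object) {
  cat("Topology tests (B =", object@B, "):\n")
  print(object@table, row.names = FALSE, digits = 4)
})

setMethod("show", "RootScanResult", function(object) {
  cat("RootScanResult:", nrow(object@candidates), "candidate root position(s);",
      "best =", object@bestId, "\n")
  print(object@candidates[, setdiff(names(object@candidates), "split")],
        row.names = FALSE, digits = 4)
})

setMethod("show", "JackknifeResult", function(object) {
  cat("Taxon-exclusion experiment:", object@R, "replicates per size\n")
  print(object@tally)
})

setMethod("show", "SearchConfig", function(object) {
  cat("SearchConfig: start =", object@startTree,
      "| tol =", object@tol, "| seed =", object@seed,
      "| constraints:", length(object@constraints), "\n")
})

#' Construct a search configuration
#'
#' @param startTree "nj" (neighbor-joining start, default) or "user".
#' @param userTree starting topology when \code{startTree = "user"}.
#' @param maxNniRounds maximum NNI improvement rounds (default 50).
#' @param tol log-likelihood convergence tolerance (default 1e-3).
#' @param seed RNG seed recorded in outputs (default 1).
#' @param constraints list of character vectors of taxon labels; each group
#'   is required to be monophyletic in the returned tree.
#' @param optimizeModel optimize gamma shape (and GTR rates) jointly with
#'   branch lengths (default TRUE).
#' @return a \code{SearchConfig}.
#' @export
searchConfig <- function(startTree = c("nj", "user"), userTree = NULL,
                         maxNniRounds = 50L, tol = 1e-3, seed = 1,
                         constraints = list(), optimizeModel = TRUE) {
  new("SearchConfig", startTree = match.arg(startTree), userTree = userTree,
      maxNniRounds = as.integer(maxNniRounds), tol = tol, seed = seed,
      constraints = constraints, optimizeModel = optimizeModel)
}
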