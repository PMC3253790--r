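#' @import methods
#' @importFrom stats optimize qnorm pnorm dnorm pchisq qgamma pgamma runif
#'   rexp cor setNames logLik
#' @importFrom utils head tail combn
NULL

setOldClass("phylo")
setOldClass("multiPhylo")

#' Partitioned multiple sequence alignment
#'
#' Taxa-by-sites character matrix together with a partition scheme mapping
#' half-open site intervals to alphabets and substitution-model tags.  An
#' unpartitioned alignment is simply a \code{PartitionedAlignment} with one
#' partition covering all sites.  Coordinates are 0-based half-open
#' internally; see \code{\link{readNexusAlignment}} for the conversion from
#' NEXUS 1-based inclusive charsets.
#'
#' @slot seqs character matrix (rows = taxa, named; columns = sites);
#'   entries are single characters, with gaps/ambiguity codes kept verbatim.
#' @slot partitions data.frame with columns \code{name}, \code{alphabet}
#'   ("nt" or "aa"), \code{start}, \code{end} (0-based half-open) and
#'   \code{model} (a model tag such as "GTR+G4" or "WAG+G4").
#' @export
setClass("PartitionedAlignment",
         representation(seqs = "matrix", partitions = "data.frame"))

setValidity("PartitionedAlignment", function(object) {
  p <- object@partitions
  m <- object@seqs
  msg <- character(0)
  if (!is.character(m)) msg <- c(msg, "seqs must be a character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "taxon names must be present and unique")
  need <- c("name", "alphabet", "start", "end", "model")
  if (!all(need %in% names(p)))
    msg <- c(msg, "partitions needs columns name, alphabet, start, end, model")
  else {
    if (nrow(p) == 0L) msg <- c(msg, "at least one partition required")
    else {
      o <- order(p$start)
      if (any(p$start[o] != c(0L, p$end[o][-nrow(p)])) ||
          p$end[o][nrow(p)] != ncol(m))
        msg <- c(msg, "partitions must be disjoint, contiguous and cover all sites")
      if (!all(p$alphabet %in% c("nt", "aa")))
        msg <- c(msg, "alphabet must be 'nt' or 'aa'")
      if (anyDuplicated(p$name)) msg <- c(msg, "partition names must be unique")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Unaligned sequence records for one gene
#'
#' Holds one or more sequence records per taxon for a single gene, e.g.
#' multiple cloned gene copies from one species, prior to choosing a single
#' representative per taxon for concatenation.
#'
#' @slot gene gene name.
#' @slot sequences named character vector: record id -> sequence string.
#' @slot taxa named character vector: record id -> taxon id.
#' @export
setClass("GeneSequenceSet",
         representation(gene = "character", sequences = "character",
                        taxa = "character"))

setValidity("GeneSequenceSet", function(object) {
  if (anyDuplicated(names(object@sequences)))
    return("record ids must be unique within a gene")
  if (!identical(names(object@sequences), names(object@taxa)))
    return("sequences and taxa must be keyed by the same record ids")
  TRUE
})

#' Reversible substitution model with discrete-gamma rates
#'
#' A time-reversible rate matrix defined by symmetric exchangeabilities S
#' and stationary frequencies pi (Q_ij = S_ij * pi_j off-diagonal, rows
#' summing to zero, normalized to one expected substitution per unit branch
#' length), plus among-site rate heterogeneity via k equal-probability
#' discrete-gamma categories with shape alpha, and an optional proportion
#' of invariant sites.
#'
#' @slot alphabet "nt" or "aa".
#' @slot states state labels in matrix order.
#' @slot exch symmetric non-negative exchangeability matrix (zero diagonal).
#' @slot freqs stationary frequencies (simplex, all > 0).
#' @slot gammaShape gamma shape alpha (> 0), or NA for rate homogeneity.
#' @slot nCat number of discrete gamma categories (>= 1).
#' @slot pInv proportion of invariant sites in [0, 1).
#' @slot name model tag, e.g. "GTR+G4".
#' @export
setClass("RateModel",
         representation(alphabet = "character", states = "character",
                        exch = "matrix", freqs = "numeric",
                        gammaShape = "numeric", nCat = "integer",
                        pInv = "numeric", name = "character"))

setValidity("RateModel", function(object) {
  k <- length(object@states)
  msg <- character(0)
  if (!all(dim(object@exch) == c(k, k)))
    msg <- c(msg, "exchangeability matrix dimension mismatch")
  else {
    if (max(abs(object@exch - t(object@exch))) > 1e-12)
      msg <- c(msg, "exchangeabilities must be symmetric")
    if (any(object@exch < 0)) msg <- c(msg, "exchangeabilities must be >= 0")
    if (any(diag(object@exch) != 0)) msg <- c(msg, "exch diagonal must be zero")
  }
  if (length(object@freqs) != k || any(object@freqs <= 0) ||
      abs(sum(object@freqs) - 1) > 1e-8)
    msg <- c(msg, "freqs must be a strictly positive simplex")
  if (!is.na(object@gammaShape) && object@gammaShape <= 0)
    msg <- c(msg, "gammaShape must be > 0")
  if (object@nCat < 1L) msg <- c(msg, "nCat must be >= 1")
  if (object@pInv < 0 || object@pInv >= 1) msg <- c(msg, "pInv must be in [0,1)")
  if (length(msg)) msg else TRUE
})

#' Fit of partitioned models on a shared topology
#'
#' A shared unrooted topology with branch lengths optimized independently
#' for each partition (fully unlinked lengths), the per-partition
#' substitution models, and the resulting total and per-site
#' log-likelihoods.
#'
#' @slot tree the shared topology (\code{ape::phylo}; edge lengths are the
#'   first partition's, kept for plotting/export convenience).
#' @slot edgeLengths list of per-partition edge length vectors aligned with
#'   \code{tree$edge} rows.
#' @slot models list of \code{RateModel}, one per partition.
#' @slot partitions the partition scheme the fit refers to.
#' @slot logLik total log-likelihood (sum over partitions).
#' @slot siteLogLik per-site log-likelihoods over the whole supermatrix.
#' @slot details list: per-partition alpha, optimizer iterations, seed.
#' @export
setClass("PartitionedModelFit",
         representation(tree = "phylo", edgeLengths = "list",
                        models = "list", partitions = "data.frame",
                        logLik = "numeric", siteLogLik = "numeric",
                        details = "list"))

#' Per-site log-likelihoods for a set of candidate topologies
#'
#' The matrix consumed by the SH and AU tests: rows are candidate
#' topologies (fits), columns are alignment sites, entries are per-site
#' log-likelihoods under each topology's own optimized parameters.
#'
#' @slot values numeric matrix, topologies x sites, rownames = topology ids.
#' @slot partitionIndex integer vector mapping each site to its partition
#'   (resampling respects these boundaries).
#' @export
setClass("SiteLogLikelihoodMatrix",
         representation(values = "matrix", partitionIndex = "integer"))

setValidity("SiteLogLikelihoodMatrix", function(object) {
  if (!all(is.finite(object@values))) return("non-finite site log-likelihoods")
  if (length(object@partitionIndex) != ncol(object@values))
    return("partitionIndex length must equal the number of sites")
  if (is.null(rownames(object@values))) return("topology ids (rownames) required")
  TRUE
})

#' Result of SH/AU topology tests
#'
#' @slot table data.frame with one row per topology: \code{id},
#'   \code{logLik}, \code{deltaLnL} (to the best), \code{pSH}, \code{pAU},
#'   and \code{auFlag} marking degenerate AU fits.
#' @slot B bootstrap replicate count.
#' @slot scales AU multiscale factors used (empty for SH-only results).
#' @slot seed RNG seed used for resampling.
#' @export
setClass("TopologyTestResult",
         representation(table = "data.frame", B = "integer",
                        scales = "numeric", seed = "numeric"))

#' Result of an outgroup root-grafting scan
#'
#' One row per candidate root branch of the fixed ingroup topology, with
#' the log-likelihood of the full tree obtained by grafting the outgroup
#' onto that branch and re-optimizing, and SH/AU p-values computed jointly
#' across all candidates.
#'
#' @slot candidates data.frame: \code{id}, \code{split} (taxa on the
#'   smaller side of the attachment bipartition, collapsed with ","),
#'   \code{logLik}, \code{deltaLnL}, \code{pSH}, \code{pAU}.
#' @slot bestId id of the maximum-likelihood candidate.
#' @slot ingroupTree fixed ingroup topology used.
#' @slot outgroupTaxa outgroup taxon labels.
#' @slot trees list of optimized full trees, one per candidate.
#' @export
setClass("RootScanResult",
         representation(candidates = "data.frame", bestId = "character",
                        ingroupTree = "phylo", outgroupTaxa = "character",
                        trees = "list"))

#' Result of the random taxon-exclusion experiment
#'
#' For each exclusion size, R replicates of: draw that many ingroup taxa at
#' random, re-infer the tree on the reduced supermatrix, and classify the
#' branch at which the outgroup attaches.  The tally mirrors a
#' size-by-root-position contingency table.
#'
#' @slot draws data.frame: \code{size}, \code{replicate}, \code{rootId},
#'   \code{excluded} (";"-collapsed taxon labels), \code{flagged}.
#' @slot tally integer matrix: exclusion sizes x observed root ids.
#' @slot sizes exclusion sizes requested.
#' @slot R replicates per size.
#' @slot seed master seed.
#' @export
setClass("JackknifeResult",
         representation(draws = "data.frame", tally = "matrix",
                        sizes = "integer", R = "integer", seed = "numeric"))

#' Configuration for maximum-likelihood tree search
#'
#' @slot startTree "nj" or "user".
#' @slot userTree optional user-supplied starting topology.
#' @slot maxNniRounds cap on NNI improvement rounds.
#' @slot tol convergence tolerance in log-likelihood units.
#' @slot seed RNG seed recorded in outputs.
#' @slot constraints optional list of taxon groups required monophyletic.
#' @slot optimizeModel whether to optimize alpha (and GTR rates).
#' @export
setClass("SearchConfig",
         representation(startTree = "character", userTree = "ANY",
                        maxNniRounds = "integer", tol = "numeric",
                        seed = "numeric", constraints = "list",
                        optimizeModel = "logical"))

setValidity("SearchConfig", function(object) {
  if (object@tol <= 0) return("tol must be > 0")
  if (!object@startTree %in% c("nj", "user")) return("startTree must be 'nj' or 'user'")
  TRUE
})
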