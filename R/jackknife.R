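## Random taxon-exclusion experiment: how stable is the inferred root
## position as ingroup taxon sampling shrinks?

#' Random taxon-exclusion experiment
#'
#' For each exclusion size and replicate, a seeded uniform draw of that
#' many ingroup taxa is removed (columns unchanged, rows dropped), the
#' tree is re-inferred on the reduced supermatrix, and the branch at which
#' the outgroup attaches is classified with the surviving group labels.
#' Size-0 replicates are deterministic and computed once.
#'
#' @param aln partitioned alignment containing ingroup and outgroup taxa.
#' @param models per-partition models.
#' @param ingroupTaxa ingroup taxon labels (exclusions are drawn from
#'   these only; the outgroup is never excluded).
#' @param sizes integer vector of exclusion sizes (each < |ingroup| - 2).
#' @param R replicates per size.
#' @param seed master seed; draws are reproducible given (seed, sizes, R).
#' @param groups named list: group name -> taxon labels, for root
#'   classification.
#' @param guard if TRUE, draws that would empty any labeled group are
#'   rejected and redrawn (off by default: plain uniform sampling).
#' @param config search configuration for the per-replicate inference.
#' @return a \code{\linkS4class{JackknifeResult}}.
#' @export
taxonExclusionExperiment <- function(aln, models = NULL, ingroupTaxa,
                                     sizes, R = 10L, seed = 1, groups,
                                     guard = FALSE,
                                     config = searchConfig(tol = 1e-2)) {
  sizes <- as.integer(sizes)
  R <- as.integer(R)
  .assert(all(sizes < length(ingroupTaxa) - 2L),
          "each exclusion size must be < |ingroup| - 2")
  .assert(R >= 1L, "R must be >= 1")
  models <- .resolveModels(aln, models)
  drawOne <- function(size) {
    if (size == 0L) return(character(0))
    for (try in 1:1000) {
      ex <- sort(sample(ingroupTaxa, size))
      if (!guard) return(ex)
      ok <- all(vapply(groups, function(g)
        length(setdiff(intersect(g, ingroupTaxa), ex)) >= 1L, logical(1)))
      if (ok) return(ex)
    }
    stop("guard unsatisfiable: cannot keep every group represented",
         call. = FALSE)
  }
  draws <- .withSeed(seed, {
    out <- list()
    for (size in sizes) for (r in seq_len(R))
      out[[length(out) + 1L]] <- list(size = size, replicate = r,
                                      excluded = drawOne(size))
    out
  })
  analyse <- function(excluded) {
    a2 <- if (length(excluded)) dropTaxa(aln, excluded) else aln
    fit <- mlSearch(a2, models, config)
    cls <- classifyRootPosition(fit@tree, setdiff(ingroupTaxa, excluded),
                                groups)
    list(id = cls$id, flagged = cls$flagged)
  }
  size0 <- NULL
  rows <- list()
  for (d in draws) {
    if (d$size == 0L) {
      if (is.null(size0)) size0 <- analyse(character(0))
      res <- size0
    } else res <- analyse(d$excluded)
    rows[[length(rows) + 1L]] <- data.frame(
      size = d$size, replicate = d$replicate, rootId = res$id,
      excluded = paste(d$excluded, collapse = ";"),
      flagged = res$flagged, stringsAsFactors = FALSE)
  }
  drawsDf <- do.call(rbind, rows)
  ids <- sort(unique(drawsDf$rootId))
  tally <- matrix(0L, length(sizes), length(ids),
                  dimnames = list(as.character(sizes), ids))
  for (i in seq_len(nrow(drawsDf)))
    tally[as.character(drawsDf$size[i]), drawsDf$rootId[i]] <-
      tally[as.character(drawsDf$size[i]), drawsDf$rootId[i]] + 1L
  new("JackknifeResult", draws = drawsDf, tally = tally, sizes = sizes,
      R = R, seed = seed)
}

#' Root-position trend across exclusion sizes
#'
#' Per exclusion size, the replicate frequency of a focal root id and of
#' an alternative id, with a Kendall-style sign statistic for the trend of
#' the focal frequency across sizes (negative = focal root recovered less
#' often as more taxa are excluded).
#'
#' @param result a \code{JackknifeResult}.
#' @param focalId the root id of interest (e.g. the full-analysis root).
#' @param altId the competing id (e.g. a fast-evolving group's stem).
#' @return list: \code{table} (size, freqFocal, freqAlt), \code{trend}
#'   (Kendall tau between size and focal frequency; NA when constant).
#' @export
summarizeRootShift <- function(result, focalId, altId = NULL) {
  tal <- result@tally
  ids <- colnames(tal)
  # an id with zero occurrences is legitimate (frequency 0 at every size)
  fr <- function(id) if (id %in% ids) tal[, id] / result@R else
    rep(0, nrow(tal))
  tab <- data.frame(size = result@sizes, freqFocal = fr(focalId),
                    freqAlt = if (is.null(altId)) NA_real_ else fr(altId))
  trend <- if (length(unique(tab$freqFocal)) == 1L) NA_real_
  else suppressWarnings(cor(tab$size, tab$freqFocal, method = "kendall"))
  list(table = tab, trend = trend)
}
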