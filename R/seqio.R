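## Alignment, partition and tree input/output.

.defaultModelTag <- function(alphabet) {
  ifelse(alphabet == "aa", "WAG+G4", "GTR+G4")
}

.makeScheme <- function(name, alphabet, start, end,
                        model = .defaultModelTag(alphabet)) {
  data.frame(name = name, alphabet = alphabet,
             start = as.integer(start), end = as.integer(end),
             model = model, stringsAsFactors = FALSE)
}

#' Construct a partitioned alignment
#'
#' @param seqs character matrix (taxa x sites) with taxon rownames, or a
#'   named character vector of equal-length sequence strings.
#' @param alphabet "nt" or "aa"; used for all partitions when
#'   \code{partitions} is NULL.
#' @param partitions optional partition scheme data.frame (columns
#'   \code{name}, \code{alphabet}, \code{start}, \code{end}, \code{model};
#'   0-based half-open intervals).  Default: a single partition spanning
#'   all sites.
#' @param name partition name used when \code{partitions} is NULL.
#' @return a \code{\linkS4class{PartitionedAlignment}}.
#' @examples
#' aln <- partitionedAlignment(c(t1 = "ACGT", t2 = "ACGA"), "nt")
#' nSites(aln)
#' @export
partitionedAlignment <- function(seqs, alphabet = c("nt", "aa"),
                                 partitions = NULL, name = "part1") {
  alphabet <- match.arg(alphabet)
  if (is.character(seqs) && !is.matrix(seqs)) {
    .assert(!is.null(names(seqs)), "sequences must be named by taxon")
    lens <- nchar(seqs)
    .assert(length(unique(lens)) == 1L, "unequal sequence lengths")
    m <- matrix(unlist(strsplit(seqs, "")), nrow = length(seqs),
                byrow = TRUE, dimnames = list(names(seqs), NULL))
    seqs <- m
  }
  if (is.null(partitions))
    partitions <- .makeScheme(name, alphabet, 0L, ncol(seqs))
  for (i in seq_len(nrow(partitions)))
    .checkAlphabet(seqs[, seq.int(partitions$start[i] + 1L, partitions$end[i]),
                        drop = FALSE],
                   partitions$alphabet[i])
  new("PartitionedAlignment", seqs = seqs, partitions = partitions)
}

.partitionSites <- function(p, i) seq.int(p$start[i] + 1L, p$end[i])

# Site -> partition index vector for an alignment.
.partitionIndex <- function(aln) {
  p <- aln@partitions
  idx <- integer(ncol(aln@seqs))
  for (i in seq_len(nrow(p))) idx[.partitionSites(p, i)] <- i
  idx
}

# Extract one partition's character matrix.
.partitionMatrix <- function(aln, i) {
  aln@seqs[, .partitionSites(aln@partitions, i), drop = FALSE]
}

#' Read FASTA sequences
#'
#' Aligned input (all records the same length) yields a
#' \code{PartitionedAlignment}; unaligned input yields a
#' \code{\linkS4class{GeneSequenceSet}} holding possibly several records
#' per taxon.  For gene sets the taxon of a record is taken from the part
#' of the header before the first "|" (so \code{"Tvag|copy2"} belongs to
#' taxon \code{"Tvag"}); headers without "|" are their own taxon.
#'
#' @param path FASTA file.
#' @param alphabet "nt" or "aa".
#' @param as "auto" (default: alignment iff equal lengths), "alignment",
#'   or "geneset".
#' @param gene gene name recorded in a returned gene set.
#' @return \code{PartitionedAlignment} or \code{GeneSequenceSet}.
#' @export
readFasta <- function(path, alphabet = c("nt", "aa"),
                      as = c("auto", "alignment", "geneset"),
                      gene = sub("\\.[^.]*$", "", basename(path))) {
  alphabet <- match.arg(alphabet)
  as <- match.arg(as)
  .assert(file.exists(path), paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  .assert(any(hdr) && hdr[1L], "not a FASTA file (no leading '>' header)")
  ids <- trimws(sub("^>", "", lines[hdr]))
  if (anyDuplicated(ids))
    stop("duplicate FASTA header(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("[[:space:]]", "", paste(x, collapse = "")),
                 character(1))
  names(seqs) <- ids
  .checkAlphabet(unlist(strsplit(seqs, "")), alphabet)
  aligned <- length(unique(nchar(seqs))) == 1L
  if (as == "alignment" && !aligned)
    stop("unequal sequence lengths in alignment FASTA", call. = FALSE)
  if (as == "alignment" || (as == "auto" && aligned))
    return(partitionedAlignment(seqs, alphabet))
  new("GeneSequenceSet", gene = gene, sequences = seqs,
      taxa = setNames(sub("\\|.*$", "", ids), ids))
}

#' Write an alignment (or gene set) as FASTA
#' @param x \code{PartitionedAlignment} or \code{GeneSequenceSet}.
#' @param path output file.
#' @param width line width for sequence wrapping.
#' @return invisibly, \code{path}.
#' @export
writeFasta <- function(x, path, width = 70L) {
  recs <- if (is(x, "PartitionedAlignment"))
    setNames(apply(x@seqs, 1L, paste, collapse = ""), rownames(x@seqs))
  else x@sequences
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(recs)) {
    writeLines(paste0(">", names(recs)[i]), con)
    s <- recs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a NEXUS alignment with optional charset partitions
#'
#' Accepts sequential and interleaved DATA/CHARACTERS blocks (via
#' \code{ape::read.nexus.data}) plus an optional SETS/ASSUMPTIONS block
#' whose \code{charset} commands (1-based inclusive NEXUS coordinates) are
#' converted to the package's 0-based half-open intervals.  A MrBayes-style
#' \code{datatype=mixed(protein:1-832,dna:833-2170)} format line assigns
#' alphabets to site ranges; otherwise the single declared datatype is
#' used for all partitions.
#'
#' @param path NEXUS file.
#' @return a \code{PartitionedAlignment} (one full-width partition when no
#'   charsets are present).
#' @export
readNexusAlignment <- function(path) {
  .assert(file.exists(path), paste("file not found:", path))
  txt <- readLines(path, warn = FALSE)
  one <- paste(txt, collapse = "\n")
  seqs <- ape::read.nexus.data(path)
  m <- do.call(rbind, lapply(seqs, function(s) toupper(s)))
  rownames(m) <- names(seqs)
  nchar_decl <- regmatches(one, regexpr("[Nn][Cc][Hh][Aa][Rr]\\s*=\\s*[0-9]+", one))
  if (length(nchar_decl)) {
    nc <- as.integer(sub(".*=\\s*", "", nchar_decl))
    .assert(ncol(m) == nc,
            sprintf("NCHAR=%d but matrix has %d columns", nc, ncol(m)))
  }
  # alphabet assignment
  mixed <- regmatches(one, regexpr(
    "[Dd][Aa][Tt][Aa][Tt][Yy][Pp][Ee]\\s*=\\s*[Mm][Ii][Xx][Ee][Dd]\\s*\\(([^)]*)\\)",
    one))
  alphaAt <- function(start, end) {  # 0-based half-open -> alphabet
    if (length(mixed)) {
      spec <- sub(".*\\(", "", sub("\\)$", "", mixed))
      parts <- strsplit(spec, ",")[[1]]
      for (p in parts) {
        kv <- strsplit(trimws(p), ":")[[1]]
        rng <- as.integer(strsplit(kv[2], "-")[[1]])
        if (start >= rng[1] - 1L && end <= rng[2])
          return(if (grepl("protein", kv[1], ignore.case = TRUE)) "aa" else "nt")
      }
      return("nt")
    }
    dt <- regmatches(one, regexpr(
      "[Dd][Aa][Tt][Aa][Tt][Yy][Pp][Ee]\\s*=\\s*[A-Za-z]+", one))
    if (length(dt) && grepl("protein", dt, ignore.case = TRUE)) "aa" else "nt"
  }
  # charsets: "charset name = 1-278;" (1-based inclusive)
  cs <- gregexpr("[Cc][Hh][Aa][Rr][Ss][Ee][Tt]\\s+[^=;]+=[^;]+;", one)[[1]]
  parts <- NULL
  if (cs[1] != -1L) {
    stmts <- regmatches(one, gregexpr(
      "[Cc][Hh][Aa][Rr][Ss][Ee][Tt]\\s+[^=;]+=[^;]+;", one))[[1]]
    rows <- lapply(stmts, function(s) {
      s <- sub(";$", "", s)
      nm <- trimws(sub("=.*$", "", sub("^[Cc][Hh][Aa][Rr][Ss][Ee][Tt]\\s+", "", s)))
      rhs <- trimws(sub("^[^=]*=", "", s))
      rng <- as.integer(strsplit(rhs, "\\s*-\\s*")[[1]])
      if (length(rng) == 1L) rng <- c(rng, rng)
      start <- rng[1] - 1L; end <- rng[2]          # to 0-based half-open
      .makeScheme(nm, alphaAt(start, end), start, end)
    })
    parts <- do.call(rbind, rows)
    parts <- parts[order(parts$start), , drop = FALSE]
  }
  if (is.null(parts))
    parts <- .makeScheme("all", alphaAt(0L, ncol(m)), 0L, ncol(m))
  partitionedAlignment(m, partitions = parts)
}

#' Write a NEXUS alignment with charsets
#' @param aln a \code{PartitionedAlignment}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeNexusAlignment <- function(aln, path) {
  m <- aln@seqs
  p <- aln@partitions
  con <- file(path, "w")
  on.exit(close(con))
  dt <- if (all(p$alphabet == "nt")) "datatype=dna"
  else if (all(p$alphabet == "aa")) "datatype=protein"
  else sprintf("datatype=mixed(%s)", paste(sprintf(
    "%s:%d-%d", ifelse(p$alphabet == "aa", "protein", "dna"),
    p$start + 1L, p$end), collapse = ","))
  writeLines(c("#NEXUS", "begin data;",
               sprintf("  dimensions ntax=%d nchar=%d;", nrow(m), ncol(m)),
               sprintf("  format %s missing=? gap=-;", dt),
               "  matrix"), con)
  wid <- max(nchar(rownames(m))) + 2L
  for (i in seq_len(nrow(m)))
    writeLines(paste0(formatC(rownames(m)[i], width = -wid),
                      paste(m[i, ], collapse = "")), con)
  writeLines(c("  ;", "end;", "begin sets;"), con)
  for (i in seq_len(nrow(p)))
    writeLines(sprintf("  charset %s = %d-%d;", p$name[i],
                       p$start[i] + 1L, p$end[i]), con)
  writeLines("end;", con)
  invisible(path)
}

#' Write a relaxed PHYLIP alignment
#' @param aln a \code{PartitionedAlignment}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePhylip <- function(aln, path) {
  m <- aln@seqs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(rownames(m)[i], paste(m[i, ], collapse = "")), con)
  invisible(path)
}

#' Parse a Newick tree string
#'
#' Thin wrapper over \code{ape::read.tree} adding the checks the rest of
#' the package relies on: unique leaf labels, finite non-negative branch
#' lengths.
#'
#' @param text Newick string (or use \code{file}).
#' @param file path to a Newick file.
#' @return an \code{ape::phylo} tree.
#' @export
parseNewick <- function(text = NULL, file = NULL) {
  phy <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(phy)) stop("malformed Newick", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(phy$edge.length)) {
    .assert(all(is.finite(phy$edge.length)), "non-finite branch length")
    .assert(all(phy$edge.length >= 0), "negative branch length")
  }
  phy
}

# Smallest tip label below each node (canonical ordering key).
.minLabelBelow <- function(phy) {
  n <- length(phy$tip.label)
  key <- character(n + phy$Nnode)
  key[seq_len(n)] <- phy$tip.label
  eo <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    p <- eo$edge[i, 1]; ch <- eo$edge[i, 2]
    if (key[p] == "" || key[ch] < key[p]) key[p] <- key[ch]
  }
  key
}

#' Write a tree as canonical Newick
#'
#' Deterministic output: at every node children are ordered by their
#' smallest descendant tip label, so identical topologies always produce
#' identical strings.  Internal node labels (e.g. bootstrap supports) are
#' emitted after the closing parenthesis.
#'
#' @param phy an \code{ape::phylo} tree.
#' @param digits decimal places for branch lengths.
#' @param file optional output path; when NULL the string is returned.
#' @return the Newick string (invisibly when writing to file).
#' @export
writeNewick <- function(phy, digits = 6L, file = NULL) {
  n <- length(phy$tip.label)
  key <- .minLabelBelow(phy)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  elen <- if (is.null(phy$edge.length)) NULL else phy$edge.length
  edgeOf <- setNames(seq_len(nrow(phy$edge)), phy$edge[, 2])
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  rec <- function(node) {
    if (node <= n) lab <- phy$tip.label[node]
    else {
      ch <- kids[[as.character(node)]]
      ch <- ch[order(key[ch], method = "radix")]
      nl <- if (!is.null(phy$node.label)) phy$node.label[node - n] else ""
      if (is.na(nl)) nl <- ""
      lab <- paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","),
                    ")", nl)
    }
    e <- edgeOf[as.character(node)]
    if (!is.na(e) && !is.null(elen)) paste0(lab, ":", fmt(elen[e])) else lab
  }
  root <- n + 1L
  out <- paste0(rec(root), ";")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Choose one representative record per taxon from a gene set
#'
#' @param geneSet a \code{GeneSequenceSet}.
#' @param policy "longest" (most non-gap characters, default), "first"
#'   (first-listed record), or "explicit".
#' @param mapping for \code{policy = "explicit"}, named character vector
#'   taxon -> record id.
#' @return named character vector: taxon id -> record id.  Ties under
#'   "longest" are broken by the lexicographically smallest record id.
#' @export
selectRepresentatives <- function(geneSet,
                                  policy = c("longest", "first", "explicit"),
                                  mapping = NULL) {
  policy <- match.arg(policy)
  taxa <- unique(unname(geneSet@taxa))
  if (policy == "explicit") {
    .assert(!is.null(mapping), "explicit policy requires a mapping")
    missing <- setdiff(mapping, names(geneSet@sequences))
    if (length(missing))
      stop("mapping references absent record(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    return(mapping[taxa])
  }
  out <- vapply(taxa, function(tx) {
    ids <- names(geneSet@taxa)[geneSet@taxa == tx]
    if (policy == "first") return(ids[1L])
    ungapped <- vapply(geneSet@sequences[ids],
                       function(s) sum(!strsplit(s, "")[[1]] %in%
                                         c("-", ".", "?")),
                       integer(1))
    ids <- ids[ungapped == max(ungapped)]
    sort(ids, method = "radix")[1L]
  }, character(1))
  setNames(out, taxa)
}

#' Concatenate per-gene alignments into a partitioned supermatrix
#'
#' Each input alignment contributes one partition (in input order).  A
#' taxon absent from a gene receives all-missing characters ("-") for that
#' partition; a taxon absent from every gene is an error.
#'
#' @param alignments named list of single-partition
#'   \code{PartitionedAlignment} objects (one per gene), each holding one
#'   sequence per taxon.
#' @param roster character vector of taxa defining row order; default is
#'   the union of all input taxa in order of first appearance.
#' @return a \code{PartitionedAlignment} whose width is the sum of the
#'   input widths.
#' @export
concatenatePartitions <- function(alignments, roster = NULL) {
  .assert(length(alignments) >= 1L, "need at least one alignment")
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    names(alignments) <- paste0("part", seq_along(alignments))
  allTaxa <- unlist(lapply(alignments, taxonNames))
  if (is.null(roster)) roster <- unique(allTaxa)
  orphan <- setdiff(roster, allTaxa)
  if (length(orphan))
    stop("taxa absent from every gene: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  blocks <- list(); schemes <- list(); at <- 0L
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    w <- nSites(a)
    blk <- matrix("-", nrow = length(roster), ncol = w,
                  dimnames = list(roster, NULL))
    keep <- intersect(roster, taxonNames(a))
    blk[keep, ] <- a@seqs[keep, , drop = FALSE]
    blocks[[i]] <- blk
    sch <- a@partitions
    schemes[[i]] <- .makeScheme(names(alignments)[i], sch$alphabet[1L],
                                at, at + w, sch$model[1L])
    at <- at + w
  }
  partitionedAlignment(do.call(cbind, blocks),
                       partitions = do.call(rbind, schemes))
}

#' Restrict an alignment to the given site intervals
#'
#' @param aln a \code{PartitionedAlignment}.
#' @param include list (or n x 2 matrix) of 0-based half-open intervals of
#'   sites to keep; intervals must be disjoint and in range.  Columns
#'   outside the intervals are removed and the partition scheme is
#'   re-indexed; partitions losing all their sites are dropped.
#' @return the masked \code{PartitionedAlignment}.
#' @export
applySiteMask <- function(aln, include) {
  if (is.matrix(include)) include <- lapply(seq_len(nrow(include)),
                                            function(i) include[i, ])
  N <- ncol(aln@seqs)
  keep <- rep(FALSE, N)
  for (iv in include) {
    .assert(length(iv) == 2L && iv[1] >= 0 && iv[2] <= N && iv[1] < iv[2],
            "interval out of range")
    sel <- seq.int(iv[1] + 1L, iv[2])
    .assert(!any(keep[sel]), "overlapping intervals")
    keep[sel] <- TRUE
  }
  p <- aln@partitions
  rows <- list()
  at <- 0L
  for (i in seq_len(nrow(p))) {
    w <- sum(keep[.partitionSites(p, i)])
    if (w > 0L) {
      rows[[length(rows) + 1L]] <- .makeScheme(p$name[i], p$alphabet[i],
                                               at, at + w, p$model[i])
      at <- at + w
    }
  }
  .assert(length(rows) > 0L, "mask removes every site")
  partitionedAlignment(aln@seqs[, keep, drop = FALSE],
                       partitions = do.call(rbind, rows))
}

#' Drop taxa (rows) from an alignment
#' @param aln a \code{PartitionedAlignment}.
#' @param taxa taxon labels to remove.
#' @return the reduced alignment (columns unchanged).
#' @export
dropTaxa <- function(aln, taxa) {
  keep <- setdiff(rownames(aln@seqs), taxa)
  .assert(length(keep) >= 2L, "fewer than two taxa would remain")
  new("PartitionedAlignment", seqs = aln@seqs[keep, , drop = FALSE],
      partitions = aln@partitions)
}
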