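## Reversible substitution models: GTR (nucleotide), WAG (amino acid),
## discrete-gamma rate heterogeneity, transition probabilities.

#' Build a normalized reversible rate matrix
#'
#' Q_ij = S_ij * pi_j for i != j, diagonal set so rows sum to zero, then
#' the whole matrix rescaled so that -sum_i pi_i Q_ii = 1, i.e. branch
#' lengths are in expected substitutions per site.
#'
#' @param S symmetric non-negative exchangeability matrix, zero diagonal.
#' @param freqs stationary frequencies (positive simplex).
#' @return the normalized rate matrix Q.
#' @export
buildRateMatrix <- function(S, freqs) {
  .assert(isTRUE(all.equal(S, t(S), tolerance = 1e-10)),
          "exchangeabilities must be symmetric")
  .assert(all(freqs > 0), "all stationary frequencies must be > 0")
  .assert(abs(sum(freqs) - 1) < 1e-8, "frequencies must sum to 1")
  Q <- S * rep(freqs, each = nrow(S))     # Q_ij = S_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))             # mean substitution rate
  .assert(mu > 0, "degenerate rate matrix (zero mean rate)")
  Q / mu
}

# Symmetric eigendecomposition of Q via the pi^{1/2} similarity transform.
# Returns the pieces needed for fast P(t) evaluation.
.eigenRateMatrix <- function(Q, freqs) {
  sq <- sqrt(freqs)
  B <- (sq * Q) %*% diag(1 / sq)          # diag(sq) Q diag(1/sq), symmetric
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  list(U = diag(1 / sq) %*% es$vectors,   # Q = U diag(lambda) Vinv
       Vinv = t(es$vectors) %*% diag(sq),
       lambda = es$values)
}

# P(t) from a cached eigendecomposition; entries clamped to [0, 1] and
# rows renormalized against round-off.
.pmat <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Vinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix
#'
#' P = exp(Q * t * rate), computed through the symmetric eigendecomposition
#' of the pi^(1/2)-similarity transform of Q (numerically stable for
#' reversible models).  Entries are clamped at 0 against round-off and rows
#' renormalized to sum to 1.
#'
#' @param model a \code{RateModel} (or a raw Q matrix with \code{freqs}).
#' @param t branch length (expected substitutions per site), >= 0.
#' @param rate rate multiplier (e.g. a gamma category rate).
#' @param freqs stationary frequencies, only when \code{model} is a raw
#'   matrix.
#' @return the transition probability matrix.
#' @export
transitionProbabilities <- function(model, t, rate = 1, freqs = NULL) {
  .assert(is.finite(t) && t >= 0, "t must be finite and >= 0")
  .assert(is.finite(rate) && rate >= 0, "rate must be finite and >= 0")
  states <- NULL
  if (is(model, "RateModel")) {
    Q <- buildRateMatrix(model@exch, model@freqs)
    freqs <- model@freqs
    states <- model@states
  } else Q <- model
  .assert(!is.null(freqs), "freqs required with a raw rate matrix")
  P <- .pmat(.eigenRateMatrix(Q, freqs), t * rate)
  if (!is.null(states)) dimnames(P) <- list(states, states)
  P
}

#' Discrete-gamma category rates
#'
#' k equal-probability categories of a Gamma(alpha, alpha) distribution
#' (mean 1); each category's rate is the conditional mean of the
#' distribution within its quantile band, computed in closed form from the
#' incomplete gamma function, then renormalized so the category mean is
#' exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of k rates with mean exactly 1.
#' @export
discretizeGamma <- function(alpha, k) {
  .assert(alpha > 0, "alpha must be > 0")
  k <- as.integer(k)
  .assert(k >= 1L, "k must be >= 1")
  if (k == 1L) return(1)
  qb <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # E[X | a < X < b] * P(a < X < b) = pgamma(b; alpha+1) - pgamma(a; alpha+1)
  # for Gamma(alpha, alpha) with mean 1.
  mass <- diff(pgamma(qb, shape = alpha + 1, rate = alpha))
  rates <- mass * k
  rates / mean(rates)
}

# Gamma category rates honouring an invariant-sites proportion: category 0
# has rate 0 with weight pInv, the k gamma categories share (1 - pInv) and
# are rescaled to keep the overall mean rate at 1.
.modelRatesWeights <- function(model) {
  k <- model@nCat
  rates <- if (is.na(model@gammaShape) || k == 1L) 1
  else discretizeGamma(model@gammaShape, k)
  w <- rep(1 / length(rates), length(rates))
  if (model@pInv > 0) {
    rates <- c(0, rates / (1 - model@pInv))
    w <- c(model@pInv, (1 - model@pInv) * w)
  }
  list(rates = rates, weights = w)
}

#' GTR nucleotide model
#'
#' General time-reversible model over \{A, C, G, T\}.  The six
#' exchangeabilities are given in the order AC, AG, AT, CG, CT, GT; the
#' G-T rate acts as the reference and is conventionally fixed at 1.
#'
#' @param rates six positive exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param freqs stationary base frequencies.
#' @param shape gamma shape alpha (NA for rate homogeneity).
#' @param nCat gamma category count (default 4).
#' @param pInv proportion of invariant sites (default 0).
#' @return a \code{RateModel}.
#' @examples
#' jc <- gtrModel()               # all rates 1, uniform frequencies = JC69
#' transitionProbabilities(jc, 0.1)
#' @export
gtrModel <- function(rates = rep(1, 6), freqs = rep(0.25, 4), shape = 1,
                     nCat = 4L, pInv = 0) {
  .assert(length(rates) == 6L && all(rates > 0), "need 6 positive rates")
  S <- matrix(0, 4, 4, dimnames = list(.NT_STATES, .NT_STATES))
  S[lower.tri(S)] <- rates  # column-wise: CA,GA,TA,GC,TC,TG = AC,AG,AT,CG,CT,GT
  S <- S + t(S)
  new("RateModel", alphabet = "nt", states = .NT_STATES, exch = S,
      freqs = setNames(as.numeric(freqs / sum(freqs)), .NT_STATES),
      gammaShape = as.numeric(shape), nCat = as.integer(nCat),
      pInv = pInv, name = .modelName("GTR", shape, nCat, pInv))
}

.modelName <- function(base, shape, nCat, pInv, empirical = FALSE) {
  nm <- base
  if (!is.na(shape) && nCat > 1L) nm <- paste0(nm, "+G", nCat)
  if (pInv > 0) nm <- paste0(nm, "+I")
  if (empirical) nm <- paste0(nm, "+F")
  nm
}

#' WAG amino-acid model
#'
#' The WAG replacement matrix with either the model's own stationary
#' frequencies (default, as in PROTGAMMAWAG-style analyses) or empirical
#' frequencies estimated from an alignment's observed residue counts with
#' a pseudocount of 0.5 per state ("+F" mode).
#'
#' @param shape gamma shape alpha (NA for rate homogeneity).
#' @param nCat gamma category count (default 4).
#' @param freqMode "model" or "empirical".
#' @param aln alignment supplying residue counts for empirical mode.
#' @param pInv proportion of invariant sites (default 0).
#' @return a \code{RateModel}.
#' @export
wagModel <- function(shape = 1, nCat = 4L, freqMode = c("model", "empirical"),
                     aln = NULL, pInv = 0) {
  freqMode <- match.arg(freqMode)
  S <- matrix(0, 20, 20, dimnames = list(.WAG_STATES, .WAG_STATES))
  S[lower.tri(S)] <- .WAG_EXCH_LOWER
  S <- S + t(S)
  if (freqMode == "model") {
    freqs <- .WAG_FREQS / sum(.WAG_FREQS)
  } else {
    .assert(!is.null(aln), "empirical mode needs an alignment")
    chars <- if (is(aln, "PartitionedAlignment")) as.vector(aln@seqs)
    else as.vector(aln)
    obs <- chars[!.isMissingChar(chars, "aa")]
    .assert(length(obs) > 0L, "empirical frequencies on empty alignment")
    counts <- table(factor(toupper(obs), levels = .WAG_STATES)) + 0.5
    freqs <- as.numeric(counts / sum(counts))
  }
  new("RateModel", alphabet = "aa", states = .WAG_STATES, exch = S,
      freqs = setNames(as.numeric(freqs), .WAG_STATES),
      gammaShape = as.numeric(shape), nCat = as.integer(nCat), pInv = pInv,
      name = .modelName("WAG", shape, nCat, pInv, freqMode == "empirical"))
}

#' Build a model from a tag string
#'
#' Understands the config dialect "GTR+G4", "WAG+G4", "WAG+G4+F", with an
#' optional "+I".
#'
#' @param tag model string.
#' @param aln alignment (needed for "+F" empirical frequencies).
#' @param shape initial gamma shape.
#' @return a \code{RateModel}.
#' @export
modelFromTag <- function(tag, aln = NULL, shape = 1) {
  parts <- strsplit(toupper(tag), "+", fixed = TRUE)[[1]]
  base <- parts[1]
  g <- grep("^G[0-9]*$", parts[-1], value = TRUE)
  nCat <- if (length(g)) max(1L, as.integer(sub("G", "", g[1]))) else 1L
  if (length(g) && is.na(nCat)) nCat <- 4L
  sh <- if (nCat > 1L) shape else NA_real_
  pInv <- if ("I" %in% parts[-1]) 0.05 else 0
  if (base == "GTR") gtrModel(shape = sh, nCat = nCat, pInv = pInv)
  else if (base == "WAG")
    wagModel(shape = sh, nCat = nCat,
             freqMode = if ("F" %in% parts[-1]) "empirical" else "model",
             aln = aln, pInv = pInv)
  else stop("unknown model tag: ", tag, call. = FALSE)
}

# Replace free parameters of a model (used by the optimizer).
.withShape <- function(model, shape) {
  model@gammaShape <- shape
  model@name <- .modelName(sub("\\+.*", "", model@name), shape, model@nCat,
                           model@pInv, grepl("\\+F", model@name))
  model
}

.gtrRateVector <- function(model) {
  S <- model@exch
  c(S["A", "C"], S["A", "G"], S["A", "T"], S["C", "G"], S["C", "T"],
    S["G", "T"])
}

.withGtrRates <- function(model, rates) {
  gtrModel(rates = rates, freqs = model@freqs, shape = model@gammaShape,
           nCat = model@nCat, pInv = model@pInv)
}
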