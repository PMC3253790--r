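---
title: "Partitioned likelihood, topology tests and root stability: methods"
author: "rootgraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned likelihood, topology tests and root stability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rootgraft)
```

This vignette documents the models, the numerical choices, and the design
decisions behind `rootgraft`, and states exactly what the synthetic-data
generator does and does not emulate.

## The model

Each partition evolves under a stationary, time-reversible Markov model.
With symmetric exchangeabilities $S$ and stationary frequencies $\pi$ the
generator is $Q_{ij} = S_{ij}\pi_j$ ($i \ne j$), diagonal set so rows sum
to zero, rescaled so $-\sum_i \pi_i Q_{ii} = 1$: branch lengths are
expected substitutions per site. Transition probabilities
$P(t) = e^{Qt}$ are computed through the symmetric eigendecomposition of
$\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$, which is
numerically stable for reversible models; entries are clamped at zero
against round-off and rows renormalized.

Among-site rate variation uses the discrete-gamma approximation with $k$
equal-probability categories of a $\Gamma(\alpha,\alpha)$ density. The
category rate is the conditional mean within the quantile band, obtained
in closed form from the incomplete-gamma identity
$E[X;\,a<X<b] = F_{\alpha+1}(b) - F_{\alpha+1}(a)$, and the rates are
renormalized to mean exactly one. Means rather than medians are used:
this is the dominant convention. Four categories is the default
throughout. A proportion of invariant sites is implemented (category of
rate zero) but off by default: the maximum-likelihood configuration this
package targets uses $+\Gamma$ only.

Supported models are GTR for nucleotides (six exchangeabilities, G–T
fixed at one as the identifiability reference) and WAG for amino acids,
with either WAG's own frequencies (default) or empirical frequencies from
the alignment with a pseudocount of 0.5 per residue (`+F`). Model tags in
partition schemes follow the config dialect `"GTR+G4"`, `"WAG+G4"`,
`"WAG+G4+F"`.

### Missing data

Gaps and all ambiguity codes are treated as fully missing: their tip
partial is a vector of ones. No partial resolution of IUPAC codes is
attempted; this is the simplest defensible convention and matches common
ML practice. An all-missing column therefore has site log-likelihood
exactly zero.

## Likelihood and optimization

Per-site log-likelihoods come from Felsenstein pruning over compressed
site patterns, with per-node rescaling (each internal partial is divided
by its per-pattern maximum and the logs accumulate in a scaler vector);
categories are combined by log-sum-exp. Correctness is pinned by an
independent brute-force oracle that enumerates all internal-state
assignments on small instances; the pruning and the oracle agree to
better than $10^{-8}$ log-likelihood units across random GTR/WAG
instances, and the likelihood is invariant to rerooting (pulley
principle) and leaf order.

Partitioned data use fully unlinked branch lengths: one length vector per
partition on the shared topology, matching the convention of optimizing
"each partition individually". A proportional-scaler mode would be a
natural future option; it is not implemented.

Branch lengths are optimized by exact coordinate ascent: for each edge
the package computes the inside (child) and outside (rest-of-tree)
partial vectors, so the likelihood as a function of that single length is
exact and cheap; Brent search in log space within $[10^{-8}, 10]$
maximizes it. Edges are swept in preorder, the outside vectors being
propagated with already-updated lengths, so every one-dimensional
optimization is exact given the current state and the total
log-likelihood never decreases. Sweeps repeat until the gain drops below
the tolerance (default $10^{-3}$; resampling-heavy analyses use
$10^{-2}$ or $10^{-1}$ where only likelihood differences between
candidates matter). Model parameters (alpha in $[0.02, 100]$, GTR rates
in $[10^{-3}, 10^3]$, both on a log scale) are optimized by bounded
coordinate ascent interleaved with length sweeps.

Tree search is best-improvement NNI hill climbing from a
neighbor-joining start (pairwise Poisson-corrected Hamming distances on
co-observed sites, $-\log(1-p)$ with $p$ capped at 0.95, negative NJ
lengths clamped to $10^{-6}$). All $2(n-3)$ neighbors are scored with
carried branch lengths; the five most promising are re-scored after
re-optimizing the rearranged edge; an accepted move triggers full
re-optimization. Ties break to the first-enumerated neighbor in a fixed
preorder of internal edges, making runs deterministic given the data and
configuration. NNI only (no SPR): adequate at the package's design scale
of tens of taxa, and a known fidelity gap relative to large-scale search
tools. Constrained searches assemble each constrained group as a subtree
in the start tree (NJ over group "super-taxa" with average linkage) and
reject NNI moves that break any constraint; nested constraints are
supported, overlapping non-nested ones are an error.

## Topology tests

All resampling respects partition boundaries — sites are drawn with
replacement within each partition, so every replicate preserves the
partition widths. This is the natural choice for partitioned models (the
alternative, pooled resampling, would let replicate partition widths
drift) and is stated here because the convention affects replicate
variance.

The SH and AU tests consume a topologies-by-sites matrix of per-site
log-likelihoods and use RELL replicates (no re-optimization). SH follows
the standard construction: center replicate totals per topology, take the
per-replicate maximum of centered values, and compare the observed
log-likelihood deficits against that null; the best topology has $p = 1$
by construction and the test is deliberately conservative. AU runs a
multiscale bootstrap over resample fractions $r \in \{0.5, \dots, 1.4\}$
(ten scales), records per-scale winning proportions, clips them to
$[1/(B+1), 1 - 1/(B+1)]$, converts to $z$-values and fits
$z(r) = d\sqrt{r} + c/\sqrt{r}$ by weighted least squares with binomial
variance weights; $p_{AU} = 1 - \Phi(d - c)$. A topology that wins or
loses every replicate at every scale is flagged (`degenerate-high`/`-low`)
and assigned $p = 1$ or $0$. Exact ties among replicate maxima (possible
when candidate topologies have identical site likelihoods) are broken at
random so that exchangeable candidates share wins symmetrically.

The composition test compares each taxon's observed state counts with
expectations from the pooled frequencies over all taxa, summed over
states, $df = \text{states} - 1$, upper-tail chi-square — the classic
composition-homogeneity screen.

## Rooting analyses

`rootScan` holds the ingroup topology fixed, grafts the outgroup subtree
onto each candidate branch (splitting it at the midpoint, initial stem
0.5 — immaterial, as lengths are re-optimized), optimizes, and compares
all candidates jointly with SH/AU. Full constrained re-search per
candidate is available behind `reSearch = TRUE`; the fixed-topology mode
is the default because the scan's comparisons only need optimized
likelihoods on a common ingroup hypothesis, and it is an order of
magnitude cheaper. The outgroup's internal arrangement is fixed (by
default its neighbor-joining tree) during the scan.

Root positions are named through user-supplied group labels: the
attachment branch's smaller side, when it is a union of complete groups,
gives ids like `"Tn"` (the stem of group Tn) or `"Tm+Tn"` (the split
dividing Tm plus Tn from the rest); other branches get explicit
`"split:taxon,taxon,..."` ids. A non-monophyletic outgroup is classified
by its first taxon's attachment and flagged.

The taxon-exclusion experiment draws uniform random subsets of ingroup
taxa (the outgroup is never excluded — exclusions target the ingroup by
design), re-infers the tree on the reduced supermatrix, classifies the
root, and tallies positions per exclusion size. Sampling is unstratified
by default, matching a plain "randomly chosen" protocol; an optional
guard rejects draws that would empty a labeled group, because root ids
are defined through surviving groups. Size-zero replicates are
deterministic and computed once.

## The synthetic-data generator

`parabasaliaScenario` builds the study design this package exists to
interrogate: six labeled ingroup clades on the fixed backbone
$((G_1,G_2),((G_3,G_4),(G_5,G_6)))$, rooted on the branch separating
$\{G_1,G_2\}$ from the rest; randomized within-group topologies
(`ape::rtree`) with branch lengths uniform in $[0.5, 1.5]$ times the
terminal (0.10) and internal (0.12) scales; an outgroup clade attached at
the root by a stem of configurable length; and one designated fast group
whose branch lengths (stem included) are multiplied by a configurable
factor. The backbone is fixed, not sampled, so the true root id is well
defined across replicates. Defaults are 6 × 4 = 24 ingroup taxa, 3
outgroup taxa, 1500 amino-acid sites under WAG+G4 — a moderate, realistic
protein-concatenation scale; the artifact regime is reached with
multiplier ≈ 3 and stem ≥ 1.5 substitutions/site.

Two regimes matter:

- **easy** (multiplier 1, stem 0.5): outgroup rooting is identifiable;
  the root scan should find the true root and the AU test should not
  reject it.
- **artifact** (multiplier 3, long stem): the long outgroup branch is
  attracted to the fast clade; as ingroup taxa are removed the frequency
  of correct rooting decays and misrootings concentrate in the fast
  clade's neighborhood (its stem, branches inside it, and the branch
  joining it to its sister) — the qualitative mechanism behind
  taxon-sampling-dependent misrooting.

What the generator does **not** emulate: indels and alignment ambiguity
(alignments are gap-free unless a uniform per-cell missingness mask is
switched on), compositional non-stationarity, heterotachy/covarion
dynamics, site-heterogeneous profile mixtures, and duplicated gene
copies. Passing tests on these simulations therefore validate the
inference machinery and the rooting logic under the fitted model class —
they do not show robustness to model violation on real data, where
site-heterogeneous models and composition tests remain necessary
diagnostics.

## Test configuration and problem sizes

The automated suite runs every analysis at desk scale, chosen once to
keep the full suite in the minutes range on a single core:

- pruning-versus-enumeration: 100 random instances, 4–6 taxa (amino-acid
  instances capped at 4 taxa — the enumeration oracle is exponential in
  internal nodes), 10–30 sites;
- topology recovery: 12 taxa, partitions of 300 + 300 nucleotide and 200
  amino-acid sites, ten seeds;
- easy-regime root recovery: 24 + 3 taxa, 300 amino-acid sites, the nine
  class-level candidate branches, five seeds, with the ingroup topology
  fixed to the generating one (topology recovery is tested separately);
- artifact regime: 24 + 3 taxa, 800 nucleotide sites, exclusion sizes
  {0, 8, 16}, three replicates per size, three experiment repetitions;
- SH calibration: 200 exchangeable-null matrices at B = 1000; AU-power
  comparison: 100 matrices.

`scripts/acceptance.R` re-runs the same battery (slightly smaller
replicate counts) from a command-line seed and writes the measured
quantities as JSON.

## Known limitations

- NNI-only search can stall on plateaus that SPR would cross; at the
  package's scale this shows up as occasional single-split errors on
  weakly supported branches.
- The AU fit is unstable for topologies with near-zero winning
  proportions at every scale; such cases are flagged rather than
  polished.
- Branch lengths are bounded at 10 substitutions/site; saturated data hit
  the bound rather than diverge.
- The NEXUS reader handles DATA/CHARACTERS blocks with sequential or
  interleaved matrices and simple `charset` statements (contiguous
  ranges); step/codon charsets are not supported.
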