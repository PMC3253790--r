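# rootgraft

Partitioned maximum-likelihood phylogenetics with a focus on one hard
question: **where is the root?** Rooting a clade by outgroup attachment is
fragile when the outgroup joins by a long branch and part of the ingroup
evolves fast — long-branch attraction can pull the root toward the
fast-evolving lineage. `rootgraft` provides the full toolchain to fit
partitioned models, to compare candidate root positions statistically, and
to measure how stable an inferred root is under taxon removal.

## What it implements

- **Substitution models**: GTR (nucleotide) and WAG (amino acid), with
  discrete-gamma rate heterogeneity. The rate matrix is
  `Q_ij = S_ij * pi_j` (off-diagonal), normalized so that
  `-sum_i pi_i Q_ii = 1` (branch lengths in expected substitutions per
  site); among-site variation uses k equal-probability categories of a
  Gamma(alpha, alpha) distribution with mean-per-quantile-band rates.
- **Likelihood**: per-site log-likelihoods by Felsenstein pruning with
  per-node rescaling; partitioned data get fully unlinked branch lengths
  and models per partition on a shared topology.
- **Inference**: exact per-edge branch-length optimization (Brent in log
  space), bounded optimization of alpha and GTR exchangeabilities, and
  best-improvement NNI hill climbing, optionally under monophyly
  constraints.
- **Topology tests**: nonparametric bootstrap supports, RELL resampling,
  the Shimodaira–Hasegawa (SH) test, and the approximately unbiased (AU)
  test (multiscale bootstrap, `z(r) = d*sqrt(r) + c/sqrt(r)`,
  `p_AU = 1 - Phi(d - c)`), plus the chi-square composition-homogeneity
  test.
- **Rooting analyses**: enumeration of candidate root branches, outgroup
  grafting with re-optimization and joint SH/AU comparison (`rootScan`),
  stepwise removal of long-branch outgroup taxa
  (`longbranchRemovalSeries`), constrained tests of group pairings
  (`constraintPairTests`), and a random taxon-exclusion experiment that
  tallies the inferred root position per exclusion size
  (`taxonExclusionExperiment`).
- **Simulation**: partitioned sequence evolution along known rooted trees,
  including a six-clade scenario generator with a designated fast group
  and a long-stem outgroup (`parabasaliaScenario`) — the regime in which
  artificial rooting arises.

## Worked example

```r
library(rootgraft)

## a six-clade world with a moderate outgroup stem (easy regime)
sc  <- parabasaliaScenario(scenarioParams(widths = c(prot = 300L)),
                           seed = 4003)
aln <- simulateScenarioAlignment(sc, seed = 4103)
ing <- ape::unroot(ape::drop.tip(sc$tree, sc$outgroupTaxa))

## scan the class-level branches as candidate root positions
cand <- enumerateRootAttachments(ing, groups = sc$groups)
deep <- cand[!grepl("^split:", cand$id), ]
rs   <- rootScan(ing, aln, NULL, sc$outgroupTaxa, candidates = deep,
                 groups = sc$groups, tol = 1e-1,
                 Bsh = 2000, Bau = 2000, seed = 4203)
rs
```

```
RootScanResult: 9 candidate root position(s); best = C+S
    id edge logLik deltaLnL    pSH      pAU
     C    1  -8025    21.47 0.1170 0.006119
     S    8  -8024    21.12 0.1165 0.005543
   C+S   15  -8003     0.00 1.0000 0.997341
 Tn+Tt   16  -8018    14.21 0.1695 0.018904
    Tn   17  -8034    31.16 0.0210 0.000000
    Tt   24  -8034    31.16 0.0210 0.000000
  H+Tm   31  -8018    14.21 0.1690 0.040884
     H   32  -8027    23.62 0.0625 0.001218
    Tm   39  -8026    22.57 0.0750 0.009683
```

The best candidate is the branch separating groups C and S from the other
four — the true root of the generating tree; the AU test does not reject
it (p = 0.997) while every alternative placement, including the stems of
the individual groups, is rejected at the 0.05 level. `classifyRootPosition()` names root positions by the
taxonomic groups on the smaller side of the attachment branch, so `"C+S"`
reads "the split dividing C plus S from the rest".

The same objects drive the stability experiment:

```r
jk <- taxonExclusionExperiment(aln, NULL, sc$ingroupTaxa,
                               sizes = c(0L, 8L, 16L), R = 3L, seed = 1,
                               groups = sc$groups)
summarizeRootShift(jk, "C+S", "Tn")
```

which returns the per-size frequency of the focal root and a Kendall-sign
trend statistic (negative when the correct root decays under exclusion).

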