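# meripModules

Detection of epitranscriptome modules from MeRIP-seq (m6A-seq) count
data with coverage-based reliability weighting.

## The problem

MeRIP-seq quantifies RNA m6A methylation by pairing an
immunoprecipitated (IP) library with an input library. For a site with
IP count *t*, input count *c* and library size factors *d_t*, *d_c*,
the methylation level is the depth-corrected IP fraction

    m = (t / d_t) / (t / d_t + c / d_c)  ∈ [0, 1].

Transcriptome coverage is extremely uneven, so many sites are measured
from a handful of reads: a site with t = 100, c = 0 and one with
t = 1, c = 0 both report m = 1, but the second number is noise.
Clustering sites into modules — groups that co-vary across conditions
because they share an m6A writer or eraser — with plain Euclidean
distance lets such unreliable measurements corrupt the analysis.

`meripModules` replaces the distance between two methylation profiles
with a reliability-weighted form

    d_w(i, j) = sqrt( Σ_s  w_{s,ij} (m_{i,s} − m_{j,s})² ),
    w ≥ 0,  Σ_s w_{s,ij} = 1,

where the weight of condition *s* for the pair (i, j) depends on the
pair coverage v_s = t_{i,s} + c_{i,s} + t_{j,s} + c_{j,s}:

* **logarithm scheme** — raw weight log(v_s + 1), normalized;
* **threshold scheme** — raw weight 1 when v_s reaches a count
  threshold (given as the α-quantile of all pairwise coverage sums),
  otherwise a reduced weight β; defaults α = 0.45, β = 0.09. Setting
  α = 0 or β = 1 reproduces the unweighted distance exactly, and
  β > 1 serves as a built-in negative control.

Around this core the package provides the standard MeRIP-seq
preprocessing pipeline (replicate merging, total-count size factors,
quantile normalization, dynamic-site selection, per-site
standardization), hierarchical clustering with an exact-match
sample-label benchmark and (α, β) grid search, hypergeometric
module-significance scoring against random modules, Fisher-exact
overlap odds ratios, and a seeded generator of MeRIP-seq-like count
data with planted modules, heterogeneous coverage and a nonspecific
background-read component.

## Worked example

```r
library(meripModules)

# synthetic MeRIP-seq data: 1000 sites, 9 conditions, 5 planted
# modules, 45% of measurements at near-zero signal coverage
sim <- simulateCounts(nSites = 1000, nConditions = 9, nModules = 5,
                      muLog = log(300), sigmaLog = 0.5,
                      lowCoverageFraction = 0.45, seed = 1)

meth <- preprocessMethylation(sim$counts, nByMean = 1000,
                              nByVariance = 800, constant = "zero")

scheme <- WeightingScheme("threshold", alphaQuantile = 0.45, beta = 0.09)
d <- pairwiseDistances(meth, scheme)
resolvedThreshold(d)
#> [1] 298

cl <- hierarchicalCluster(d, k = 5, linkage = "ward")
truth <- sim$truth$siteModules[rownames(methLevels(meth))]
adjustedRand(clusterLabels(cl), truth)
#> [1] 0.4560779

# the same data without reliability weighting
dPlain <- pairwiseDistances(meth, WeightingScheme("none"))
adjustedRand(clusterLabels(hierarchicalCluster(dPlain, k = 5,
                                               linkage = "ward")), truth)
#> [1] 0.2697745
```

The resolved threshold (298 reads here) is the empirical 45% quantile
of all pairwise coverage sums: pair measurements below it get weight
β = 0.09. With nearly half of all measurements corrupted, recovery of
the planted modules is necessarily partial, but weighting lifts the
adjusted Rand index from 0.27 to 0.46 against the planted truth; at
high coverage the same pipeline recovers planted modules almost
perfectly (ARI ≥ 0.9; see the acceptance tests).

The 6-sample benchmark, the grid search and enrichment scoring follow
the same pattern; see the methods vignette
(`vignettes/measurement-weighting.Rmd`) and the CLI
(`inst/scripts/meripmodules`) for the end-to-end pipeline
(`runPipeline()`).

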