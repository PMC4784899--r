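# gelnetx

Network-regularized sparse linear models for genomics: an implementation
of the **generalized elastic net** (GELnet), plus the synthetic benchmark
and evaluation protocol that diagnose *when a gene network actually helps
prediction*.

## The problem

Genomic prediction tasks are chronically under-sampled: tens of thousands
of gene-level features, a few dozen samples.  Sparse linear models help,
but the selected genes are often an arbitrary pick among correlated
alternatives and resist biological interpretation.  Gene interaction
networks encode which features belong together mechanistically; the
generalized elastic net injects that knowledge directly into the
regularizer:

    R(w) = lambda1 * sum_j d_j |w_j|  +  (lambda2 / 2) * w' P w

with per-feature L1 weights `d_j >= 0` and a positive semi-definite
feature-pair penalty `P`.  Taking `P` as the (normalized) graph Laplacian
penalizes weight differences across network edges; taking `P = I - D`
with `D` a diffusion kernel extends the reach beyond immediate neighbors;
`d = 1, P = I` recovers the classical elastic net exactly.  The objective

    (1/2n) * sum_i a_i (y_i - w'x_i - b)^2 + R(w)

is minimized by cyclic coordinate descent with soft-thresholding (C++
core), with exact zero-coordinate skipping, a KKT-certified stopping
rule, and a closed-form `lambda1Max()` bound anchoring sparsity grids.
Binary logistic regression and sparse network-regularized principal
components reduce to the same solver (`gelnetLogistic()`, `gelnetPCA()`).

Who it is for: anyone fitting penalized linear models on expression-like
data who has a feature network (Pathway Commons, STRING, a co-expression
graph) and wants to know whether that prior is pulling its weight.

## Worked example

Simulate the benchmark's network-coupled scenario (a 500-node scale-free
network, a 50-gene pathway selected by random walk, expression from a
Gaussian graphical model whose conditional-independence graph *is* the
network, response `y = X w_true`), then compare the GELnet against the
elastic net at matched sparsity over the marginalization grid:

```r
library(gelnetx)

cfg <- simulationConfig(p = 500, n = 50, seed = 7)
ds  <- simulateDataset(cfg, "GGM+")
ds
#> SyntheticDataset [GGM+]: 50 samples x 500 features, pathway size 50

cmp <- runComparison(ds, nPairs = 50, seed = 7)
cmp
#> GELnetComparison over 15 grid cells
#>       method reconstruction     rmse dispersion
#>  elastic_net      0.9534822 5.690062  0.6300182
#>       gelnet      0.9577898 5.602388  0.6042464
#> percent improvement (GELnet over elastic net):
#> reconstruction           rmse     dispersion
#>          -0.45           1.54           4.09
```

Reading the output: both methods are fit on a 3 x 5 grid of
`lambda1` (fractions of `lambda1Max`) by `lambda2` values and the three
metrics are averaged over the grid rather than tuned.  Here the network
prior buys a 1.5% better leave-pair-out RMSE and a 4.1% tighter
clustering of the selected genes on the network (dispersion), at matched
sparsity per grid cell — the positive control working as intended.
`networkRelevance(cmp)` applies the decision rule (at least 2.5% RMSE or
5% dispersion improvement); at this desk scale the improvements sit just
under those thresholds, which were calibrated on the full-size study —
see the methods vignette for why small networks compress the contrast.

Corrupt the network before handing it to the GELnet and the edge decays:

```r
tbl <- scrambleSweep(simulationConfig(p = 500, n = 50),
                     fractions = seq(0, 1, 0.1), nRuns = 10, seed = 1)
scrambleEdge(tbl)   # largest fraction with GELnet RMSE <= elastic net's
```

A thin command-line wrapper over the same functions ships in
`inst/cli/gelnetx.R` (`simulate`, `fit`, `logistic`, `pca`, `evaluate`,
`sweep` subcommands, all seed-deterministic).

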