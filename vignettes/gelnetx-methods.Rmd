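---
title: "Network-regularized linear models with gelnetx: methods and design"
author: "gelnetx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-regularized linear models with gelnetx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelnetx)
```

## The model

`gelnetx` fits linear models $h(x) = w^T x + b$ under the generalized
elastic net regularizer

$$R(w) \;=\; \lambda_1 \sum_j d_j |w_j| \;+\; \frac{\lambda_2}{2}\, w^T P w,$$

a strict generalization of the classical elastic net ($d = 1$, $P = I$).
The per-feature weights $d_j \ge 0$ let individual features be penalized
more or less; the positive semi-definite matrix $P$ penalizes *pairs* of
features.  Because $P$ multiplies an L2 term, it should encode
**dissimilarity**: a small $P_{ij}$ (or a negative one, within PSD limits)
makes it cheap for features $i$ and $j$ to carry weight together.  For a
gene interaction network this steers sparse solutions toward connected,
mechanistically interpretable gene sets.

Supported constructions of $P$ from a network with adjacency $A$:

* **Laplacian** $L = \mathrm{Diag}(A\mathbf{1}) - A$, whose quadratic form
  is $w^T L w = \tfrac12 \sum_{ij} A_{ij} (w_i - w_j)^2$ — it penalizes
  weight differences across edges (`laplacianPenalty()`).
* **Normalized Laplacian** $\tilde L$, with unit diagonal and
  $-A_{ij}/\sqrt{d_i d_j}$ off the diagonal.  Isolated nodes keep a
  diagonal entry of 1, so $\tilde L$ restricted to any set of mutually
  non-adjacent nodes is exactly an identity submatrix.  This convention
  makes the dispersion metric (below) equal 1 for fully scattered
  selections.
* **Diffusion penalty** $P = I - D$ with $D = \exp(-tL)$ the heat kernel
  (`diffusionPenalty()`).  All eigenvalues of $D$ lie in $(0, 1]$, so $P$
  is PSD.  Unlike $L$, the kernel sees beyond immediate neighbors; the
  diffusion time `t` (default 0.1) controls the horizon and is exposed
  as a parameter because no single value suits every network scale.
* **NICK penalty** $P = I + \beta L$, a ridge/Laplacian blend
  (`nickPenalty()`), and the **pseudo-inverse** of any PSD kernel
  (`kernelPenalty()`), which converts a similarity kernel into the
  dissimilarity form the L2 term expects; for a graph Laplacian,
  $(L^+)^+ = L$.

Penalty matrices are validated at construction: symmetry within $10^{-10}$
and smallest eigenvalue $\ge -10^{-8}$ times the spectral norm.
Violations are errors; eigenvalues are never clipped silently, because a
quietly "repaired" penalty would change the objective without warning.

## The solver

`gelnetFit()` minimizes the weighted least-squares objective

$$\frac{1}{2n}\sum_i a_i\,(y_i - w^T x_i - b)^2 + R(w)$$

by cyclic coordinate descent.  Each coordinate update is available in
closed form via the soft-threshold operator, with the residual vector and
$Pw$ maintained incrementally; the bias is refreshed after every sweep as
the weighted mean of the residuals.  Design choices that matter:

* **Sweep order** is fixed ascending feature index — deterministic and
  reproducible; no randomized shuffling.
* **Convergence** requires the per-sweep objective change to drop below
  `tol` (default $10^{-5}$, absolute; a relative mode is available) *and*
  the first-order optimality (KKT) residuals to be below `10 * tol`.
  The second condition matters: an objective can stall a sweep early
  while a coefficient is still drifting, and the KKT check certifies the
  returned model rather than the trajectory.
* **Zero-coordinate caching.**  A weight snapped to zero stays at zero
  unless its soft-threshold argument escapes $\lambda_1 d_k$, so such
  coordinates are skipped without touching the cached residuals.
  Skipping leaves every state vector bitwise untouched, and the test
  suite asserts bit-identity between the cached and naive paths.
* **Degenerate columns** (identically zero with $\lambda_2 P_{kk} = 0$)
  have no defined update; they are frozen at zero with a warning rather
  than raising an error, because constant columns routinely survive
  filtering in genomic matrices.
* $\lambda_1^{\max}$ (`lambda1Max()`) uses the *absolute value* of the
  weighted feature–residual inner product.  Without the absolute value
  the zero-model guarantee fails for features negatively correlated with
  the response, which a brute-force grid check confirms.

The solver core is C++ (via RcppArmadillo), which keeps the
grid-of-penalties studies below within interactive runtimes.

## Reductions

**Logistic regression** (`gelnetLogistic()`) reduces to the squared-error
solver through the usual second-order expansion: at the current fit,
sample weights $a_i = p_i(1-p_i)$ and working responses
$z_i = \eta_i + (y_i - p_i)/a_i$ define a weighted least-squares problem
solved with a warm start; the outer loop monitors the penalized negative
log-likelihood.  The weights are clipped from below at `probClip`
($10^{-5}$) so that near-saturated probabilities cannot zero out a
coordinate-update denominator.

**Sparse penalized PCA** (`gelnetPCA()`) handles the ratio-of-quadratic
forms objective with the linearize–solve–normalize iteration: map the
current loading through the covariance, solve the penalized linear
subproblem exactly by coordinate descent, and rescale to unit norm.
With vanishing penalties this is power iteration and recovers the leading
eigenvector; the L1 term sparsifies the loading, and a network penalty
pulls it toward connected gene sets.  $\lambda_2$ must be positive
because it supplies the curvature of the subproblem.  The loading sign is
fixed (largest-magnitude entry positive) for reproducibility, and
`deflate()` orthogonalizes the data against accepted components so
further components can be extracted.  Whether successive components
should be forced orthogonal is genuinely open; deflation is provided but
not mandatory.

## The synthetic benchmark

The simulation module asks a practical question: *when does a network
prior actually help?*  Its default parameters are the study conditions:
$p = 5000$ features, $n = 50$ samples, pathway covering 10% of nodes,
preferential attachment with $m = 2$ (the generator is parameterized
because real interactomes are scale-free but no specific growth model is
canonical), GGM ridge $\delta = 0.1$, noiseless response.

1. A scale-free network is grown; a "pathway" is selected by a simple
   random walk until 10% of the nodes are collected, giving a connected
   0/1 weight vector $w$.
2. Expression is drawn $X \sim N(0, S)$.  In the **GGM** scenarios the
   precision matrix is $\Omega = (\lambda_{\max}(A) + \delta) I - A$:
   positive definite by construction, with off-diagonal support *exactly*
   equal to the network's edges, so the conditional-independence graph of
   the data is the network itself (the generator certifies this by
   re-inversion).  The sign matters and was chosen deliberately.  A
   ridge-shifted precision can carry the adjacency with either sign; the
   form above makes adjacent features *positively* partially correlated,
   which is how genes in a shared pathway actually co-express, and in our
   experiments it is the variant under which the network prior behaves as
   designed (the GELnet's marginalized cross-validated RMSE and
   dispersion improve over the elastic net whenever the true network is
   supplied).  The opposite sign ($\Omega = A + cI$, adjacent features
   conditionally *anti*-correlated) makes the network prior fight the
   data's correlation structure and erases the RMSE and dispersion edge
   while leaving only a reconstruction-error advantage — a useful
   negative diagnostic, but not the biology the benchmark means to
   emulate.  In the **Rand** scenarios a Wishart-style covariance
   $GG^T/p + 10^{-3} I$ replaces $S$: the data then carry no relation to
   the network.
3. The response is the exact pathway activity $y = Xw$ (a `noiseSd` knob
   exists because noiseless $p \gg n$ regression is degenerate for some
   downstream consumers, but 0 is the study condition).
4. The learner receives either the true network (`+` scenarios) or a
   scrambled one (`-`): a random symmetric permutation of rows and
   columns that preserves the degree multiset — global topology intact,
   feature-level identities destroyed.  `scrambleNetwork()` generalizes
   this to partial corruption ("scramble factor").

What the generator does *not* emulate: count noise and mean–variance
coupling of sequencing assays, batch effects, or multi-omic feature
layers.  Passing benchmarks here shows the machinery behaves as designed
under a Gaussian, network-faithful world; it does not certify
performance on any particular real assay.

## Evaluation protocol

Three metrics, each looking at a different failure mode:

* **Reconstruction error** $1 - \cos^2(w_{\text{true}}, \hat w)$ —
  scale-invariant; 1 by convention when $\hat w = 0$.  The squared cosine
  is used because the natural normalization by two quadratic forms makes
  only the squared numerator unit-consistent.
* **RMSE**, $\sqrt{\text{mean}((y - \hat y)^2)}$, estimated by
  **leave-pair-out cross-validation**: pairs of samples are held out,
  predicted, and all held-out errors pooled.  All $\binom{n}{2}$ pairs
  are enumerated when there are at most `nPairs`; otherwise `nPairs`
  pairs are sampled under the governing seed.  The root-mean-square form
  is used; only relative comparisons between methods matter.
* **Dispersion** $\sum_{i,j \in Z} \tilde L_{ij} / |Z|$ over the selected
  set $Z$ — at most 1, exactly 1 when $Z$ has no internal edges, lower
  the more the selection clusters on the network.  An empty selection is
  an error, not a score.

`runComparison()` marginalizes over the penalty grid rather than tuning:
$\lambda_2 \in \{10^4, 10^3, 10^2, 10, 1\}$ crossed with $\lambda_1 \in
\{\lambda_1^{\max}/27, \lambda_1^{\max}/9, \lambda_1^{\max}/3\}$ for the
elastic net.  Each GELnet cell reuses the elastic net's nonzero count as
a target and finds its own $\lambda_1$ by bisection (30-step budget,
exact matches preferred, ties resolved toward the sparser solution) —
comparing methods at matched sparsity isolates the effect of the network
penalty from the effect of model size.  Percent improvements
$100(\text{EN} - \text{GELnet})/\text{EN}$ of the marginal means
summarize a run, and `networkRelevance()` encodes the decision rule: a
network prior is flagged relevant at $\ge 2.5\%$ RMSE improvement or
$\ge 5\%$ dispersion improvement (a conservative mode requires both).

`scrambleSweep()` repeats the GGM comparison while the supplied network
is corrupted by increasing scramble factors; `scrambleEdge()` reports
the largest corruption level at which the GELnet's marginalized RMSE is
still no worse than the elastic net's.  Since the elastic-net arm does
not depend on the scramble fraction it is computed once per run and
shared across fractions — identical numbers, roughly half the cost.

### Problem sizes used by the shipped studies

The packaged tests and the acceptance study run the benchmark at
$p = 500$, $n = 50$, 10 runs, with 50 sampled LPOCV pairs per grid cell
— sizes chosen so a full scramble sweep completes in minutes on one
core while keeping $p \gg n$ and a 50-node connected pathway.  Two
consequences of this desk scale are worth knowing.  First, the densest
grid cells ($\lambda_1^{\max}/27$) select most of the 500 nodes, which
compresses the dispersion contrast between the two arms relative to a
5000-node network where any selection is sparse.  Second, per-run
metric differences are noisier; conclusions are therefore drawn from
across-run means of the marginalized estimates, not from single cells.

## Numerical choices and known limitations

* Diffusion kernels are computed by symmetric eigendecomposition of
  $L$, not series expansion — exact for the sizes targeted here
  ($p \lesssim 10^4$ dense).
* `ggmCovariance()` refuses silently ill-posed input: the Cholesky
  factorization of $\Omega$ must succeed, and the support certificate is
  computed by explicit re-inversion.
* Random draws accept an optional `seed` and run under
  `withr::with_seed()`, leaving the session RNG untouched; omitting the
  seed uses (and advances) the session RNG as usual.
* The logistic outer loop is not a strict descent method; three
  consecutive likelihood increases flag the fit as not converged instead
  of looping forever.
* `lambda1Max()` assumes at least one $d_j > 0$; an all-zero $d$ leaves
  the L1 term void and the bound undefined (error).
* Kernelized feature maps, directed/signed networks, multi-class
  logistic models and hinge-loss training are out of scope; the NICK
  *penalty* is provided, but SVM training is not.
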