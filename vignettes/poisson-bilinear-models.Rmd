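---
title: "Poisson bilinear models for single-cell counts: model, estimation, and uncertainty"
author: "scBilinear authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson bilinear models for single-cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scBilinear)
```

## The model

scBilinear models a genes x cells matrix of UMI counts directly, without a
preliminary normalization or transformation step:

$$
Y_{ij} \sim \mathrm{Poisson}(\mu_{ij}), \qquad
\log \mu_{ij} = \alpha_i + \beta_j + \sum_{m=1}^{M} \sigma_m u_{im} v_{jm}.
$$

The gene intercepts $\alpha_i$ absorb baseline expression, the cell
intercepts $\beta_j$ absorb sequencing depth, and the rank-$M$ interaction
$X = U\Sigma V^\top$ captures structured biological variation on the log
scale. When the link is the identity and the outcome Gaussian, $U$,
$\Sigma$, $V$ would be the ordinary PCA solution, so the model can be read
as PCA inside the link function of a Poisson GLM. A Poisson outcome is
used deliberately: the technical sampling noise of UMI counts is close to
Poisson, and apparent overdispersion largely reflects biological
heterogeneity that the factors are supposed to capture, not discard.
An $\mathrm{Exponential}(\tau)$ prior on each $\sigma_m$ (equivalently a
nuclear-norm penalty $\tau\|X\|_*$, since $\|X\|_* = \sum_m \sigma_m$ in
canonical form) is available for stability; the default is $\tau = 0$, the
unpenalized MLE, which is the natural comparison target for other
estimators of the same model.

### Identifiability and the canonical form

The factorization is only identified up to invertible recombinations, so
every fit is reported in a canonical form: $U^\top U = V^\top V = I_M$,
$\sigma_1 \ge \cdots \ge \sigma_M > 0$ (components thresholded to zero are
dropped), and the largest-magnitude entry of each loading column is
positive. `canonicalizeFit()` converts any raw factorization to this form
while preserving the mean matrix exactly; this matters because tests and
downstream consumers may compare means across reparameterizations.

One gauge freedom remains: a rank-1 component aligned with the all-ones
direction of either side is indistinguishable from an intercept shift.
We resolve it inside the fitting loop rather than in `canonicalizeFit()`:
with `centerFactors = TRUE` (the default) the working matrix is doubly
centered before each SVD step and the removed row/column means are folded
into the intercepts, so the fitted factors are orthogonal to the intercept
directions throughout. Centering a *finished* rank-$M$ interaction and
re-truncating it would change the fitted means (double centering can raise
the rank by up to two), which is why the canonicalizer itself never
centers: it would violate its own mean-preservation contract. The flag
exists because exact-reproduction experiments of the uncentered update
are occasionally useful.

## Estimation: iteratively reweighted SVD

A second-order Taylor expansion of the log-posterior at the current
estimates turns the maximization into a weighted low-rank problem with
weights $W_{ij} = \hat\mu_{ij}/\hat\mu_*$ ($\hat\mu_*$ the largest fitted
mean) and working response $Z_{ij} = \hat X_{ij} + (Y_{ij} -
\hat\mu_{ij})/\hat\mu_{ij}$. The weighted problem is solved by repeatedly
applying

$$
\hat X \leftarrow \mathrm{SVD}_{M,\tau}\!\big(\hat X + W \circ (Z - \hat X)\big),
$$

where $\mathrm{SVD}_{M,\tau}$ is the rank-$M$ truncated SVD with singular
values soft-thresholded by $\tau$. The identity $W \circ (Z - \hat X) =
(Y - \hat\mu)/\hat\mu_*$ means the update needs a single dense working
array and never materializes $Z$. With $\hat X$ fixed, the intercepts have
closed-form conditional MLEs, each vector updatable in one vectorized
sweep ($\alpha$ first, then $\beta$). One outer iteration is:
`innerSteps` applications of the SVD update with $W$ and $Z$ frozen,
double centering folded in on the last one, then one intercept sweep.

Numerical choices that matter:

* **Convergence** is declared when the relative change of the penalized
  log-posterior, $|\Delta \mathrm{obj}|/(|\mathrm{obj}|+1)$, falls below
  `tol` (default `1e-6`). Parameter-change criteria are avoided because
  the flat directions of the likelihood make them noisy.
* **Monotonicity safeguard.** The Taylor surrogate does not guarantee
  ascent. The objective is evaluated every outer iteration; on a drop
  larger than `1e-8` the interaction step is halved (convex combination of
  old and new, re-truncated to rank $M$) up to five times, and the best
  iterate seen is what a non-converged call returns, with a warning —
  never silently.
* **Step size and `innerSteps`.** The update moves each entry at rate
  $W_{ij} \le 1$, so convergence slows when the fitted means span many
  orders of magnitude (large $\hat\mu_*$). Because the inner update holds
  $W$ and $Z$ fixed, extra inner applications are much cheaper than full
  outer iterations (no exponentials, no intercept refits) and progress
  about as far per application; the default is `innerSteps = 5`. Strong
  signals at small matrix sizes can still need thousands of effective
  steps — the worked sizes below state what the tests use.
* **Truncated SVD.** Small problems use LAPACK directly. Larger ones use
  subspace iteration warm-started on the previous iteration's row basis
  with two power steps and four columns of oversampling; the working
  matrix changes slowly across iterations, so the warm start keeps the
  factorization accurate, and the objective monitor would catch any
  inexactness that mattered.
* **Overflow cap.** Linear predictors are capped at 30 on the natural-log
  scale ($e^{30} \approx 10^{13}$); exceeding the cap is an error naming
  the offending gene and cell rather than a silent overflow.
* **Degenerate inputs.** Genes with all-zero counts and cells with zero
  totals have intercept MLEs at $-\infty$; `fitGBM()` refuses them and
  `filterZeroMargins()` drops them with a message. `M = 0` is valid and
  reproduces the closed-form margin-product model, which is also the
  initialization (cell intercepts $\log S_j$ centered, gene intercepts
  their conditional closed form, $X = 0$) — the same base model that
  underlies analytic Pearson residuals.

## Scaling by projection

`fitGBMProjected()` estimates $(\alpha, U, \Sigma)$ on a random subset of
cells, then fits each cell independently: with those frozen, column $j$ is
an ordinary Poisson GLM with design $[1, U]$, offset $\alpha$, and
coefficients $(\beta_j, \sigma_1 v_{j1}, \ldots, \sigma_M v_{jM})$, fit
here by a dedicated IRLS (at most 25 steps, coefficient tolerance
`1e-8`) and cross-checked in the tests against `glm()`. All cells —
including subset cells — are refit by projection so the score matrix has a
single provenance (`keepSubsetScores = TRUE` restores the subset fit's
scores instead). The projected $V$ is a stack of per-cell MLEs and is
deliberately **not** re-orthonormalized, which would destroy the per-cell
GLM interpretation; such fits carry `projected = TRUE` and downstream
cluster assessment operates on $V\Sigma$ regardless. Columns are processed
one at a time, so memory stays bounded in the number of cells, and the
per-cell fits are embarrassingly parallel by construction (no parallel
backend is imposed).

## Uncertainty in the scores

The Fisher information block for cell $j$'s scores is
$F_j = (U\Sigma)^\top \mathrm{diag}(\mu_{\cdot j}) (U\Sigma)$, and
$\mathrm{se}(\hat v_{jm}) = \sqrt{[F_j^{-1}]_{mm}}$ with the fitted means
plugged in. This block approximation treats $\alpha$, $\beta$, $U$,
$\Sigma$ as known and therefore *underestimates* the uncertainty; in the
package's own simulations the empirical coverage of 95% normal-theory
intervals sits slightly below the nominal level (the acceptance checks
accept \[0.85, 0.97\] pooled over cells and factors). Loading standard
errors use the same code path transposed. Numerically singular blocks fall
back to a pseudo-inverse and are flagged rather than dropped.

## Cluster cohesion index

Clustering single-cell embeddings routinely produces clusters on data with
no structure at all. The cluster cohesion index (CCI) asks how stable a
given clustering is under the score uncertainty: draw $\tilde v_{jm} \sim
N(\hat v_{jm}, \mathrm{se}^2)$ independently, recluster the perturbed
scores with the *identical* method descriptor (same backend, same k, same
resolution; a fresh seed each repetition so algorithmic stochasticity is
included), and record, for each pair of original clusters $(k, k')$, the
fraction of cell pairs that land in a common cluster again. Averaged over
repetitions (default 100), the diagonal is the CCI and the off-diagonal
the inter-cluster cohesion index; the diagonal of the returned matrix
equals the CCI vector by construction, singleton clusters are `NA`.
Clustering operates on the scaled scores $V\Sigma$ (the representation one
plots), so the standard errors are scaled by $\sigma_m$ accordingly. The
pair-level averaging follows the plain reading of "fraction of pairs of
cells"; a per-cell weighting would be a different, also defensible,
choice.

The significance threshold comes from the null model $V = 0$, under which
the means collapse to $\exp(\alpha_i + \beta_j)$. The default
(`cciNullThreshold(method = "refit")`) simulates whole null count matrices
from those means and sends each through the *identical* pipeline — fit,
standard errors, clustering, CCI — so the null CCIs carry the same
SVD-extracted spurious structure a real fit produces on unstructured
data. Because a dataset is flagged when *any* of its clusters clears the
threshold, the threshold is the 0.95 quantile of the per-replicate
maximum CCI. A cheaper score-level variant (`method = "scores"`), which
draws null scores directly as $N(0, \mathrm{se}^2)$ and pools per-cluster
fractions, is also provided; it understates the cohesion of fitted null
structure (fitted null scores are SVD-optimized, not white) and its
threshold is measurably anti-conservative, so it is for exploration only.

The default clustering backend is a k-nearest-neighbour graph (Euclidean,
k = 20, symmetrized) with Louvain community detection at resolution 0.8 —
the default pipeline of the major single-cell toolkits. A k-means backend
exists mainly to make exactness tests deterministic.

## The simulators, and what they do not emulate

* `simulateGBM(I, J, M, kappa)` draws $U$ and $V$ uniformly (Haar) from
  the Stiefel manifold via sign-fixed QR of a Gaussian matrix, sets
  $\sigma_m = (\kappa m / M)(\sqrt I + \sqrt J)$ — $\kappa = 2$ is the
  low-latent-variability regime, $\kappa = 5$ high — draws intercepts
  i.i.d. standard normal, and samples Poisson counts. The truth is
  returned in canonical form (singular values re-sorted decreasing; the
  spanned subspace is unchanged).
* `simulateMarkerGenes()` builds the four-cell-type, two-marker benchmark:
  998 noise genes at Poisson(1), rare types A and B (25 cells each),
  common C and D (475 each), gene 1 means (50, 5, 150, 150) and gene 2
  means (1, 1, 1, 120). The exact means are this package's own defaults
  consistent with the qualitative design (moderate/low/high/high and
  low/low/low/high, two rare types of 25 cells); all are configurable.
  The depths are chosen on information grounds, not realism: a contrast
  carried by one gene across 25 rare cells must exceed the singular-value
  noise floor of a 1000 x 1000 count matrix, roughly
  $\|X \sqrt{\mu}\| \gtrsim (IJ)^{1/4}$, to be recoverable by *any*
  factorization — at low depths (common-type means around 10) the gene-1
  contrast falls well short of that floor, the second fitted factor locks
  onto noise, and no method can separate the rare types. At the default
  depths the likelihood keeps both markers, while the fixed
  pseudo-dispersion of analytic Pearson residuals ($\theta = 100$)
  inflates the denominator at high means and pushes the gene-1 signal
  below the leading noise eigenvalue of the residual matrix — which is
  precisely the failure mode the benchmark exists to exhibit.
* `simulateNullPoisson()` is the structure-free null.

All three produce clean Poisson counts with exchangeable cells. Real data
violate this in ways the simulators deliberately do not emulate: ambient
RNA, doublets, batch effects, cell-cycle structure, and gene-gene
correlation beyond rank-$M$. Tests passing on these generators show the
estimator and its uncertainty calibration are correct under the model,
not that the model captures everything in real tissue.

## Evaluation tooling

`subspaceDistance()` is the Frobenius norm of the difference of the
orthogonal projectors onto two column spaces, computed from QR bases
(never materializing the J x J projectors); orthogonal rank-$M$ subspaces
sit at $\sqrt{2M}$. `countSplit()` thins counts binomially (p = 1/2 by
default) into two halves that always sum to the original and are
independent under Poisson sampling, enabling honest train/test evaluation
via `oosLogLik()` (constants removed; an oracle variant accepts the true
means in place of held-out counts). The baselines `logPCA()` (size-factor
log transform, median library size or fixed $10^4$ with row
standardization) and `aprPCA()` (analytic Pearson residuals with
$\theta = 100$) use gene-wise mean centering before the SVD — standard
practice, stated here because reasonable implementations differ — and no
highly-variable-gene selection anywhere, matching how the benchmarks are
defined.

## Problem sizes used in the checks

The packaged tests run fits at up to 300 genes x 1000 cells (rank 5),
500 x 500 for interval coverage (20 replicate fits), and 1000 x 1000 for
the marker benchmark; the cluster-cohesion calibration uses 25
perturbation repetitions and 10 data seeds. These sizes were chosen so the
whole suite exercises every claim at meaningful signal-to-noise on a
single core; all of them are one `fitGBM()` call away from being rerun
larger.

One known behavior worth stating plainly: at the 300 x 1000, $\kappa = 2$,
$M = 5$ design, the weakest factor's per-entry information is of the same
order as the score magnitude itself, so the subspace distance between the
fitted and generating $V$ plateaus around 1.3–1.8 (out of a random-subspace
baseline of $\sqrt{10} \approx 3.16$) *for any estimator* — the fitted
$\hat V$ is much closer to the truth than chance but cannot pin down the
weakest directions at this size. The likelihood also keeps increasing
slightly past the truth (mild overfitting of the weak components), which
is why the convergence tolerance, not a distance target, defines when to
stop.

## Known limitations

* The number of factors $M$ must be chosen by the user; no selection
  heuristic is shipped.
* The block Fisher standard errors are anti-conservative by construction;
  joint $U$–$V$ uncertainty with the identifiability constraints is out of
  scope (and expensive).
* The dense working array means memory scales with $I \times J$ for the
  full fit; use `fitGBMProjected()` when cells are plentiful.
* Negative binomial or zero-inflated outcomes are deliberately not
  offered; apparent overdispersion is treated as signal for the factors.
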