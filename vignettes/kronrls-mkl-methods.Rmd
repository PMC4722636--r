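---
title: "KronRLS-MKL: model, design choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KronRLS-MKL: model, design choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kronrlsmkl)
```

## The model

Drug–target interaction prediction is treated as link prediction on a
bipartite network. With drugs $d_1,\dots,d_{n_d}$, targets
$t_1,\dots,t_{n_t}$ and binary labels $y \in \{0,1\}^{n}$ over all
$n = n_d n_t$ pairs, regularized least squares minimizes

$$J(f) = \frac{1}{2n}\sum_i (y_i - f(x_i))^2 +
         \frac{\lambda}{2}\|f\|_K^2,$$

whose dual solution solves $(K + \lambda I)a = y$ for the pairwise kernel
$K$. Taking $K = K_D \otimes K_T$ (the product kernel over pairs) and
exploiting that the eigendecomposition of a Kronecker product factorizes,
the solve costs one eigendecomposition per side instead of an
$n \times n$ system. `kronrls()` implements exactly this route and the
test suite pins it, on dozens of random small instances, against the
dense $(K_D \otimes K_T + \lambda I)$ solve to $10^{-8}$.

The MKL extension learns one convex combination of base kernels per side,
$K_D^* = \sum_i \beta_D^i K_D^i$ and $K_T^* = \sum_j \beta_T^j K_T^j$.
`kronrls_mkl()` alternates the closed-form dual solve with two per-side
weight subproblems on the residual target $u = y - \lambda a / 2$:

$$\min_{\beta \in \Delta} \frac{1}{2\lambda n}
  \lVert u - m\,\beta\rVert_2^2 + \sigma \lVert\beta\rVert_2^2,$$

where column $i$ of the design $m$ is the vectorized score contribution
of kernel $i$ given the current dual coefficients and the other side's
combination, and $\Delta$ is the probability simplex.

Two deliberate interpretations are baked in. First, the weights are
constrained to the simplex: the unconstrained least-squares reading would
not yield a convex combination, and the method's selling point is
interpretable convex weights. Second, the data-fit term is minimized in
its *squared* Frobenius form — smooth, strictly convex for $\sigma > 0$,
and consistent with the joint objective the alternation is derived from.

### Orientation and indexing conventions

`Y` is stored targets × drugs and `vec` is R's native column-major
stacking, so `a = as.vector(A)` and `pair_index(d, t, n_t) =
(d-1) n_t + t` (1-based). Under this convention the eigendecomposition
solution reads $A = Q_T C Q_D^\top$ with
$C_{ij} = M_{ij} / (\Lambda_T(i)\Lambda_D(j) + \lambda)$,
$M = Q_T^\top Y Q_D$, with no transposes left to juggle. The convention
is not a free choice of documentation: it is verified numerically by the
brute-force Kronecker oracle test, which would fail loudly under any
transposed reading.

### The weight subproblem solver

The subproblem is a tiny convex quadratic program (at most ~10 weights in
any realistic kernel collection). It is solved exactly by active-set
enumeration: for every support the equality-constrained KKT system is
solved in closed form, infeasible candidates are discarded, and the best
feasible candidate wins, ties broken by enumeration order. This is
deterministic, has no convergence tolerance to tune, and for
rank-deficient systems (duplicate kernels at $\sigma = 0$) falls back to
the minimum-norm solution, which splits weight evenly across identical
columns. The contract — agreement with a $10^{-4}$-resolution grid search
over the 1-simplex — is what the tests assert, not the algorithm.

### What is and is not monotone

Each $\beta$-step is an argmin, so it can only improve its own
subproblem objective; this is asserted per step. Joint monotonicity of
the full objective across alternations is *not* asserted: the dual step
minimizes the ridge objective, not the joint MKL objective, so small
non-monotonicities across alternations are possible and expected. The
trace recorded in every fit makes this inspectable.

## Hyperparameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `lambda` | ridge regularization of the dual solve | 1 | reference selection grid $2^{-15}, 2^{-10}, \dots, 2^{30}$ |
| `sigma` | L2 pull on the kernel weights | 0.25 | reference grid $0, 0.25, 0.5, 0.75, 1$; large values push weights to uniform $1/P$ |
| `max_iter` | alternations | 20 | convergence is typically reached in < 5 |
| `tol` | max-norm weight change to declare convergence | $10^{-4}$ | |
| `init` | starting weights | uniform | |

Defaults for `max_iter`, `tol` and the uniform start are the package's
own choices; the grids are the reference protocol's.

## Kernels computed in-package

**GIP.** The Gaussian Interaction Profile kernel compares binary
interaction profiles, $K(u,v) = \exp(-\gamma\|y_u - y_v\|^2)$ with
$\gamma$ = multiplier / mean squared profile norm. Inside
cross-validation it must be computed from the fold's *masked* network
(test cells zeroed); an entity with an all-zero training profile then
gets off-diagonal similarity $\exp(-\gamma\|y_v\|^2)$ by the formula
itself, with no special-casing. The bandwidth multiplier (default 1) is
exposed because published usages differ.

**PPI shortest-path similarity.** Hop distances on a protein–protein
network are converted to similarities $S = A e^{-bD}$ with published
parameters $A = 0.9$, $b = 1$, zero for unreachable pairs. The
*growing*-exponent variant $Ae^{+bD}$ appears in print but rewards
distance, which contradicts the notion of similarity; the decaying form
is the default and the sign is selectable via the `decay` argument.
Proteins absent from the edge list are isolated: similarity $A$ to
themselves, 0 to everything else.

**KA ideal kernel.** The kernel-alignment heuristic is defined for a
label vector, but here labels live on pairs while kernels are
entity-by-entity. The ideal kernel is therefore lifted to the entity
side as the Gram matrix of interaction profiles ($Y^\top Y$ for drugs,
$YY^\top$ for targets) — the natural lift of $yy^\top$. Negative
alignments are floored at zero so KA weights remain convex. Whether the
original heuristic used this lift, a pairwise ideal kernel, or something
else is not documented anywhere we could verify; this choice is recorded
here rather than asserted as the original authors'.

## Evaluation protocol

Three scenarios: `pair` folds all $n_d n_t$ pairs; `new_drug` /
`new_target` fold entities, so held-out entities are entirely absent
from training (cold start). Every fold is audited programmatically for
leakage before fitting. Pair-scenario training *zeroes* the held-out
cells rather than masking the loss: the RLS formulation has no per-cell
weights, and zeroing-as-unknown is the standard KronRLS convention.
Whether the pair scenario should fold all pairs or only known
interactions is ambiguous in common usage; the package folds all pairs
(the balanced variant then subsamples negatives from the test fold), and
`subsample_negatives()` exposes the ratio.

AUPR is computed as non-interpolated average precision with tie blocks
(tied scores are evaluated at the end of their block). The metric name
alone does not pin an estimator; average precision is the standard
choice and the implementation is pinned against an independent
$O(n^2)$ rank-walk oracle. A random scorer on balanced labels lands near
0.5, which the suite checks as a sanity band.

Nested selection uses an inner 3-fold plan (the package's choice, to
keep nested runs desk-scale) of the same scenario, picks the grid point
with the best mean inner AUPR (ties → first in declared grid order, for
determinism), and refits on the full outer training view. The λ grid is
read as exponents $-15, -10, \dots, 30$ — ten points.

## The synthetic generator

`simulate_dti()` draws latent factor vectors per entity, marks the
top-scoring pairs as interactions (thresholded to hit the requested
density exactly), and builds kernels as cosine-normalized Gram matrices:
of the true factors (informative), of independent factors (irrelevant),
or convex mixes (noisy). All kernels are PSD with unit diagonal by
construction, mimicking the value ranges of normalized similarity
kernels. The defaults — a 60 × 40 grid at 6.41 % density with one
informative and three irrelevant kernels per side — encode the package's
reference study conditions: the density mirrors the class imbalance of
the smallest public drug–target gold-standard network, and the kernel
configuration is the canonical weight-recovery setting in which a
correct MKL method should concentrate weight on the informative kernel.
The headline synthetic test asserts exactly that, on 10 generator seeds
per side.

What the generator does *not* emulate: the heavy-tailed degree
distributions, block structure and correlated kernel collections of real
chemogenomic data, nor any chemistry- or sequence-specific statistics.
Passing the synthetic tests therefore demonstrates algorithmic
correctness and weight-recovery behavior under the stated generative
model — not predictive performance on real pharmacological data.

`plant_hyperparameter_signal()` supports selection-recovery experiments:
it inflates each kernel's diagonal (default ridge 0.5), which lowers the
kernel's effective signal-to-noise ratio so that both interpolation
(tiny λ) and the unregularized smoother limit (huge λ) degrade — giving
the held-out AUPR-versus-λ curve a sharp interior maximum — and then
rescales all kernels so the measured optimum lands on the requested
target (scaling the pairwise kernel by $s$ shifts the whole ridge path
by $s$). The calibration curve is averaged over all folds of a pair
split because a single-split argmax proved unstable between adjacent
grid points.

## Numerical choices and degenerate inputs

* Kernels are symmetrized on load, $(K + K^\top)/2$: real similarity
  files carry floating-point asymmetry and the solver assumes symmetry.
* `make_psd()` repairs indefinite similarity matrices; `clip` (zeroing
  negative eigenvalues, tolerance $10^{-8}$) is the default and least
  distorting repair. The solver itself only warns below $-10^{-8}$,
  since the eigendecomposition route is defined for any symmetric
  matrix.
* No kernel normalization (unit trace/diagonal) is applied by the
  solvers; kernels are used as given.
* All randomness (fold plans, subsampling, the generator) flows from
  explicit integer seeds through `withr::with_seed`; no global RNG state
  is consumed, and identical inputs give bit-identical traces.
* Degenerate cases with defined behavior: single-kernel MKL reduces
  exactly to KronRLS; an all-zero label matrix gives a zero dual; an
  all-zero interaction matrix makes the GIP bandwidth undefined and is
  an error; a single-class test fold is an AUPR error (and nested
  selection treats a failing grid point as $-\infty$).

## Problem sizes

The test suite and acceptance checks run at deliberate desk scale: oracle
equivalences on grids up to 6 × 6 (where the dense Kronecker system is
cheap), weight recovery on the 60 × 40 reference conditions, protocol
checks on grids around 15 × 12, and the class-imbalance arithmetic on
networks generated at the four gold-standard shapes up to 445 × 664.
The solvers themselves are dense and comfortably handle the few-hundred
by few-hundred scale of the public benchmark datasets.

## Known limitations

* No sparsity-promoting (L1) weight variant and no joint non-alternating
  optimization; the weight path is only as good as the alternation.
* Dense linear algebra throughout; grids beyond a few thousand entities
  per side would need iterative or factorized variants.
* The KA ideal-kernel lift and the pair-scenario folding convention are
  documented interpretations of under-specified conventions, not
  community-settled standards.
* AUPR is the only headline metric; ROC-AUC is deliberately not
  reported for imbalanced link prediction.
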