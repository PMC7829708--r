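---
title: "Minimum disparity estimation for discrete and mixed-scale data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum disparity estimation for discrete and mixed-scale data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindisp)
```

## The estimation problem

Given data density `d` (observed cell proportions, or a kernel density
estimate) and a parametric model `m_β`, a minimum disparity estimator
minimises

$$\rho(d, m_\beta) = \sum_x G(\delta(x))\, m_\beta(x), \qquad
  \delta(x) = \frac{d(x)}{m_\beta(x)} - 1,$$

over β, for a convex `G` with `G(0) = 0`. The Pearson residual δ lives in
\([-1, \infty)\): δ = −1 is an empty cell the model expected to be
populated, large δ is an inflated cell. Every disparity carries a residual
adjustment function `A(δ) = (1+δ)G′(δ) − G(δ)`, standardised so that
`A(0) = 0` and `A′(0) = 1`, and the estimating equations are weighted score
equations with weights

$$w(\delta) = \min\!\left\{\frac{[A(\delta) + 1]_+}{\delta + 1},\, 1\right\}
  \in [0, 1].$$

Two structural facts drive everything in this package:

* **Efficiency.** Near δ = 0 every standardised RAF looks like the identity,
  so at the model the estimators share the MLE's influence function
  (verified numerically by `influence_curve()` against
  `fisher_information()`): no asymptotic efficiency is sacrificed.
* **Robustness.** At large |δ| the RAFs of HD and SCS grow much more slowly
  than the identity, so `w(δ)` falls and surprising observations are
  discounted. The LD (`A(δ) = δ`, `w ≡ 1`) is exactly the MLE and serves as
  the non-robust reference.

`disparity_family()` provides LD, HD, PCS, SCS, NCS in closed form and the
Cressie–Read family `CR:λ` for generic λ ∉ {0, −1}. Closed forms rather
than λ-limits are used at the named members because the CR expression is
singular at λ ∈ {0, −1}; all named forms are cross-validated in the tests
against numerical differentiation of `G`. The SCS raw RAF
`2δ(3δ+4)/(δ+2)²` has slope 2 at zero and is divided by that constant for
the standardised `raf()`; the optimiser gradients use the unstandardised
form, which is the exact derivative of the objective.

## Case 1: two-way tables

For an R×C table the model is the saturated independence model
`m(y)·π(x)` — no structure beyond independence is imposed, so the
"parameters" are the two marginal probability vectors themselves. The fit
minimises the disparity subject to both vectors lying on the unit simplex.

**Solver.** The simplex constraints are absorbed by a multinomial-logit
reparameterisation (reference level = last), giving a smooth unconstrained
problem. It is solved by quasi-Newton (`nlminb`) with the analytic gradient
`∂ρ/∂(\text{cell mass}) = −A_{\text{raw}}(δ)`, then polished by a few
damped Newton steps on the gradient (finite-difference Hessian of an
8-parameter problem), which brings the stationarity residual to ~1e−11.
The fit is declared converged when the maximum gradient component is below
`grad_tol = 1e−8`; otherwise up to 5 random restarts are tried and a
non-convergence error carrying the best iterate is raised. Initial values
are independent uniform draws normalised to the simplex — the objective is
well behaved enough that results are insensitive to the start, which the
restart logic makes cheap to verify. An interior-point path cannot return
exact 0/1 boundary estimates; logits are clamped at ±30 (probabilities
within ~1e−13 of the boundary), which is far beyond anything the study
designs produce.

**Empty cells.** A zero count against positive model mass gives δ = −1
exactly. `G`, `A`, `w` are evaluated as right limits there (for the LD the
continuous extension `G(−1) = 1`), keeping the objective finite for
structural zeros. For the LD specifically, `patch_zero_cells()` replaces
exact-zero counts by 1e−8 before fitting, so the Kullback–Leibler objective
and score stay well behaved; the other distances need no patch and handle
the empty cell through their weights (the HD and SCS weight of an empty
cell is 0, the PCS weight is 1 — one sees the consequences directly in the
structural-zero scenario, where HD/SCS pull the affected marginal furthest
from the raw proportion).

**Checking a fit.** `estimating_equation_residual()` evaluates the weighted
score in the reduced parameterisation `m_1..m_{R−1}, π_1..π_{C−1}` (the
reduction avoids Lagrange multipliers in the check); its norm is ~0 at a
fit. `pi_update()` exposes the explicit weighted-proportion update for π
used by the alternating variant of the algorithm; the package's primary
path is the joint constrained minimisation, which needs no alternation.

## Case 2: categorical × continuous

With `X` categorical (K levels) and `Y` a d-variate continuous vector
assumed independent of `X`, the model is `π_x · N(μ, Σ)` with Σ treated as
known (identity by default); the estimated parameters are `(π, μ)`. Both
densities are smoothed with a mean-zero normal kernel of covariance `H`:

* the data side is the kernel density estimate
  `f*(y) = (1/n) Σ_i φ_H(y − y_i)`, pooled across groups (under
  independence all groups share the continuous distribution);
* the model side uses the transparency of the normal kernel:
  `N(μ, Σ) * φ_H = N(μ, Σ + H)` exactly, evaluated in closed form.

The residual is `δ(x, y) = f*(y)(n_x/n) / (m*(y) π_x) − 1` and the
objective `Σ_x π_x ∫ G(δ(x,y)) m*(y) dy` is evaluated by a tensor-product
composite Simpson 1/3 rule. The same logit-plus-quasi-Newton machinery as
Case 1 does the optimisation, with μ unconstrained and the analytic
gradient reusing `−A_raw(δ)`.

**Tunable parameters.**

* **Bandwidth** `H` (squared units of `Y`): the diagonal normal-reference
  plug-in `H_jj = (4/(n(d+2)))^{2/(d+4)} s_j²`, estimated once from the
  data and held fixed during optimisation. This is the standard
  density-estimation choice, deliberately *not* robustified: part of what
  the simulations measure is how much contamination a default bandwidth
  tolerates. Contamination inflates `s_j²` and hence `H`, and a larger
  bandwidth blurs the contaminant into the main mode, which is the main
  driver of bias at high contamination; smaller bandwidths reduce that bias
  at some efficiency cost. `options$bandwidth` overrides the default.
* **Integration grid**: uniform per-dimension nodes (odd count ≥ 3) over
  `[min(Y_j) − 4√H_jj, max(Y_j) + 4√H_jj]`, 41 nodes per dimension by
  default and 21 in Monte-Carlo mode. The grid bounds follow the data, so
  fits are translation equivariant. The `SmoothedField` normalisation check
  (Simpson integral of each density ≈ 1) guards against an undersized grid;
  a data-mass capture below 0.95 is an error.
* **Numerical floors**: `m*` is floored at 1e−300 before division so far
  tails (where `f*` is also ≈ 0) cannot produce 0/0.
* **Initial values**: π from normalised uniform draws, each `μ_j` uniform
  between the first and third sample quartiles of `Y_j` — wide enough to
  probe for multiple roots, narrow enough to stay near the data.

## The synthetic-data generators

The generators are first-class, tested code; they define the study
conditions under which all quantitative claims in the tests hold.

**Tables.** Six multinomial designs with fixed total N: a balanced 5×5
(all cells 1/25), a balanced 2×3, two independence designs from printed
marginal vectors (`III`, `IV`), and two structural-zero designs. The
structural-zero cell matrices are *reconstructions*: the study reports the
marginals (through the LD estimates) but not the cell matrix, so `IIa`
takes the product of the reported marginals and transfers the (1,1) mass
within the table so the marginals are preserved exactly while `P[1,1] = 0`;
for `IIb` the two zero cells plus the reported marginals determine every
cell uniquely. These choices pin the LD means exactly in expectation; the
non-LD point values under the zero-cell designs therefore depend on the
reconstruction and are checked qualitatively (strongest zero-cell control
by HD), not numerically.

**Mixed samples.** A latent `(Z_0, Z_1..Z_d) ~ MVN(0, Σ)` with unit
diagonal and polyserial correlation ρ between `Z_0` and each `Z_j`; `X` is
the tertile bin of `Z_0` (equal-probability normal-quantile thresholds —
the category probabilities are stated, the thresholds follow from them) and
`Y = μ + Z_{1..d}`. Contamination replaces each observation's continuous
part independently with probability 1−α by a draw from `N(μ_c, I)`; the
categorical part is never contaminated. The generator reproduces marginal
normality, the mixture mean, and the latent correlation (tested via the
point-polyserial shrinkage identity).

What the generators do **not** emulate: dependence between `X` and the
shape (not just location) of `Y`'s distribution, non-normal continuous
parts, heteroscedastic groups, and real-data artefacts such as rounding or
missingness. Passing tests certify behaviour under the stated designs, not
under arbitrary real data.

## The Monte-Carlo harness

`run_mc_table()` / `run_mc_mixed()` repeat generate → (patch) → fit,
summarising per-parameter means, SDs, Monte-Carlo standard errors, biases
and the overall absolute bias `Σ_ℓ |θ̄_ℓ − θ_{0ℓ}|`. Each replicate's data
come from a named substream of the root seed (a Lehmer-style mixing of
(seed, index)), so summaries are bit-identical across runs and independent
of execution order; fits get their own substreams so a failed fit's retry
cannot shift another replicate's data. Failed replicates are retried once
and otherwise counted; a run with more than 5% failures is flagged invalid.

The default study sizes in the tests and the acceptance script are
scaled-down choices the package makes for desk-scale reproducibility:
500 replicates for the table study and 100 for the mixed study (with ±3
Monte-Carlo-standard-error tolerances carrying the reduced precision), and
a 21³ Simpson grid in Monte-Carlo mode. The original-scale settings
(10 000 / 1000 replicates, finer grids) are plain function arguments.

## Known limitations

* Only the independence model is fitted for tables; log-linear structure
  with interactions is out of scope, as are φ-divergence goodness-of-fit
  test statistics.
* The mixed case assumes `X ⟂ Y` and a known (identity) covariance; group
  specific continuous distributions and covariance estimation are not
  implemented. The continuous × continuous case is likewise out of scope.
* PCS downweights nothing for inflated cells (its weight is 1 for all
  δ > 0); it is included as a classical reference, not as a robust choice.
* With heavy contamination the disparity objective can have several local
  minima; the solver reports the root it converges to from its (seeded)
  start, as is standard for these estimators. `weight_report()` makes the
  chosen root auditable.
* At the saturated independence model a *single* inflated cell can be
  partly absorbed by the marginal parameters rather than downweighted;
  the weights are most informative against a hypothesised (fixed) model,
  and `pearson_residuals_table()` accepts any model for exactly that use.

## Diagnostics

`fisher_information()` gives the asymptotic covariance at the fit (the
estimators are asymptotically normal with variance `I(β₀)⁻¹`);
`influence_curve()` verifies robustness/efficiency claims by refitting
under point-mass contamination over ε ∈ {0.02, 0.01, 0.005} and Richardson
extrapolating the derivative at ε = 0 — at the model it reproduces the MLE
influence `I⁻¹u` to ~1e−6, and its extrapolation-error estimate is part of
the returned object. `weight_report()` ranks cells/observations by
ascending weight; `autoplot()` methods visualise the weight map, the
per-observation weights, and Monte-Carlo summaries.
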