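# mindisp

Minimum disparity (φ-divergence) estimation for discrete and mixed-scale
data: robust, first-order efficient alternatives to maximum likelihood for
two-way contingency tables and for samples that mix a categorical variable
with a multivariate continuous one (e.g. diagnostic codes plus laboratory
measurements). It is aimed at biostatisticians and methodologists who need
parameter estimates that are not dragged around by a handful of surprising
cells or observations, together with diagnostics that say *which* cells or
observations were surprising.

## The method

A disparity between the observed proportions `d` and a model `m_β` is

    ρ(d, m_β) = Σ G(δ) · m_β,      δ = d / m_β − 1  (the Pearson residual),

with `G` convex and `G(0) = 0`. Choices of `G` give the familiar distances:

| id  | distance                        | G(δ)                    |
|-----|---------------------------------|-------------------------|
| LD  | likelihood disparity (the MLE)  | (1+δ)log(1+δ) − δ       |
| HD  | twice-squared Hellinger         | 2(√(1+δ) − 1)²          |
| PCS | Pearson chi-squared / 2         | δ²/2                    |
| SCS | symmetric chi-squared           | 2δ²/(δ+2)               |
| CR(λ) | Cressie–Read power divergence | ((1+δ)^{λ+1} − 1)/(λ(λ+1)) |

Estimation minimises `ρ` over the model parameters. Differentiating shows
the estimating equations are *weighted* likelihood score equations with
weights `w(δ) = min{[A(δ)+1]₊ / (δ+1), 1}`, where
`A(δ) = (1+δ)G′(δ) − G(δ)` is the residual adjustment function standardised
to `A(0) = 0`, `A′(0) = 1`. For the LD, `A(δ) = δ` and `w ≡ 1`: the MLE.
For the robust families, `w < 1` on surprising cells (probabilistic
outliers), which bounds their influence while the estimator keeps the MLE's
influence function — hence full asymptotic efficiency — at the model.

Two data situations are implemented:

* **Both variables discrete** (`fit_table()`): the independence model
  `m(y)·π(x)` is fitted to an R×C table under unit-sum constraints on both
  probability vectors, with residuals `δ(y,x) = n_yx/(N m(y) π(x)) − 1`.
* **Categorical × continuous** (`fit_mixed()`): the data density is
  kernel-smoothed (normal kernel, normal-reference diagonal bandwidth) and
  matched against the smoothed model. The normal kernel is *transparent*
  for the normal model — `N(μ, Σ) * N(0, H) = N(μ, Σ + H)` exactly — so no
  information is lost and no numerical convolution is needed. Integrals are
  evaluated by a tensor-product composite Simpson 1/3 rule.

Synthetic-data generators (`gen_table()`, `gen_mixed()`) reproduce the
simulation designs the estimators were studied under — balanced and
structural-zero multinomial tables, fixed-marginal independence tables, and
latent-normal ordinal + trivariate-normal samples with polyserial
correlation and normal contamination mixtures — and `run_mc_table()` /
`run_mc_mixed()` drive reproducible Monte-Carlo summaries of bias and SD.

## Worked example

Fit the independence model to a 5×5 table drawn from a design with a
structural zero at cell (1,1), by twice-squared Hellinger distance:

```r
library(mindisp)
set.seed(42)
tab <- gen_table("IIa", N = 1000)     # multinomial draw, P[1,1] = 0
fit <- fit_table(tab, "HD")
tidy(fit)
#>    term  estimate std.error
#>  1 m1      0.0333   0.00567
#>  2 m2      0.197    0.0126
#>  3 m3      0.202    0.0127
#>  4 m4      0.210    0.0129
#>  5 m5      0.357   NA
#>  6 pi1     0.170    0.0119
#>  ...
head(weight_report(fit), 3)
#>       y     x count  delta weight
#> 1     1     1     0 -1      0
#> 2     1     4     5 -0.421  0.901
#> 3     1     3    11  0.994  0.915
```

The HD estimate of the first row probability (0.033) sits below the
marginal proportion because the empty cell is genuinely incompatible with
independence; the weight report shows it is the most surprising cell
(`w = 0`) and is effectively removed from the estimating equations.
`std.error` comes from the inverse Fisher information (the reference levels
are the unit-sum remainders). `autoplot(fit)` draws the weight map.

For mixed-scale data with 5% of the continuous part contaminated at
(3,3,3):

```r
set.seed(1)
dat <- gen_mixed(mixed_scenario(mu = c(0,0,0), alpha = 0.95, mu_c = c(3,3,3)), N = 1000)
fit <- fit_mixed(dat, "HD", options = list(grid_nodes = 21))
fit
#> <mixed_disparity_fit> family = HD, objective = 0.128039, converged = TRUE
#>   pi: 0.326 0.336 0.338
#>   mu: -0.004405  0.049081  0.023806
colMeans(dat$values)
#> 0.137 0.187 0.175
```

The sample means are pulled ~0.15 toward the contaminant; the minimum
Hellinger estimates stay within 0.05 of the truth.

A thin command-line wrapper over the same functions ships in
`inst/cli/mindisp.R` (`fit-table`, `fit-mixed`, `simulate-data`,
`simulate`, `diagnose`).

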