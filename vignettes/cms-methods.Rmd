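---
title: "Moderated mediation with composite mediators: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated mediation with composite mediators: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmsem)
```

## Why a dedicated estimator

A composite (emergent variable) is an exact weighted linear combination of
observed components. Unlike a reflective latent variable, it has no
construct-level error term: the construct *is* its components, and removing a
component changes its meaning. Classical SEM interaction estimators assume
reflective measurement throughout, and the usual workarounds for formative
constructs either fix the weights in advance or cannot place the composite in
an endogenous position — which is exactly where a mediator sits. `cmsem`
implements a three-step estimator that keeps the weights free, lets the
composite be a mediator, and still delivers full-information ML inference for
the latent interaction.

## Step 1: the composite/factor model

For a composite with `K` ordered components, `K` composites are extracted:
the composite of interest plus `K − 1` *excrescent* variables that absorb the
component variance and covariance the composite of interest does not carry.
Rather than weights, the model is parameterized by composite loadings: with
`W` the matrix of weights, the components satisfy `c = Λ (C, ν)′` with
`Λ = (W′)⁻¹`. Identification uses the banded pattern produced by
`build_ho_pattern()`:

* one loading per composite fixed to one — we fix the **diagonal**, matching
  the worked 3-component example pattern `[[1, λ12, 0], [λ21, 1, λ23],
  [λ31, 0, 1]]`; the alternative of fixing construct variances to one was
  rejected to stay on the printed-example scale,
* each excrescent variable relates to exactly two adjacent components,
* each component loads on at most two excrescent variables,
* excrescent variables are uncorrelated with every composite of interest and
  latent variable (and with other blocks' excrescent variables), but may
  covary freely among themselves within a block,
* the composite of interest must relate to at least one variable outside its
  block.

Component order is taken verbatim from the user's declaration; reordering
changes the band pattern but not the span of the composite of interest.

`fit_ccfa()` fits this model jointly with the reflective blocks by minimizing
the ML discrepancy `F = log|Σ(θ)| + tr(S Σ(θ)⁻¹) − log|S| − p`, with **all**
construct covariances free (a saturated structural part — no structural
restrictions leak into the measurement estimates). Latent blocks are scaled
by fixing their first loading to one. Variance parameters are left
unconstrained on purpose: Heywood cases must surface as negative estimates so
the admissibility screen can catch them, not be silently clipped at zero.

Numerical design: the discrepancy gradient is analytic
(`dF = tr[(Σ⁻¹ − Σ⁻¹SΣ⁻¹) dΣ]`), optimization is BFGS with Newton polishing
until the gradient infinity-norm falls below `1e-8` (up to three
restart rounds; BFGS alone can stall on the flat ridges this likelihood
develops in small samples when an excrescent loading approaches zero and its
variance compensates). Starting values matter on those ridges: the
composite-of-interest loadings are started from the components' covariances
with the variables outside the block (proportional to the loadings under the
model), and the excrescent cells from a closed-form banded factorization of
the residual component covariance, with a sign-flipped generic fallback.
A fit that still ends with gradient norm above tolerance is flagged
non-converged and therefore inadmissible.

## Step 2: weights and scores

`loadings_to_weights()` inverts the estimated loading matrix,
`Ŵ = (Λ̂′)⁻¹`; `first_column_weights()` provides the closed alternating-sign
cofactor form of the first column for banded matrices. The printed general
form of the last entry of that expression is internally inconsistent with the
row recursion (it repeats the diagonal element where the band element
belongs); we follow the recursion, and the package's authority is the exact
equality with the generic transpose-inverse, which is enforced by tests over
random banded matrices of orders 2–8. Weight extraction refuses loading
matrices with condition number above `1e12` — beyond that the weights are
numerical noise.

`compute_scores()` mean-centers the components with the analysis sample's
own means (population means are not assumed known) and applies the weights,
so the score has mean zero and no intercepts are needed for observed
variables downstream. Scores are *not* rescaled to unit variance here;
standardization happens once, at the reporting stage, to avoid double
standardization.

## Step 3: the latent interaction likelihood

With the mediator replaced by its score `m`, the model has one nonlinear
latent dimension: conditional on the standardized latent predictor `X = x`,
every observed variable is Gaussian —

* predictor indicators: mean `λ_x x`, diagonal error covariance,
* score: mean `a x`, variance `Var(ζ_M)`,
* outcome indicators: the outcome construct has mean
  `τ + b x + (c + d x) a x`, and the slope `(c + d x)` propagates the score
  residual variance into the outcome block covariance.

The marginal likelihood integrates these conditional densities over
`x ~ N(0, 1)` with a Gauss–Hermite rule whose weights are normalized to sum
to one. The default of **24 nodes** was chosen because refitting with 48
nodes moves estimates by less than `1e-4` at n = 500 (a tested property);
the likelihood itself agrees with a 64-node rule to better than `1e-6` per
observation. The scale constraints are: latent predictor variance fixed to 1
(the population predictor is standardized), outcome scale fixed by its first
loading. The score equation is estimated **jointly** in the same likelihood
(full information), not as a side regression. Mean-centering of the product
term is implicit: the single free intercept `τ` absorbs the `−d·Cov(X, M)`
shift, so centered data need no further intercepts.

Maximization is direct quasi-Newton on the quadrature likelihood with
finite-difference gradients evaluated in compiled code, followed by Newton
polishing with the numeric observed-information Hessian. The cited EM scheme
for this class of models reaches the same optimum; a single well-polished
quasi-Newton path was simpler to make robust, and the Hessian is needed for
the standard errors anyway. Non-positive variance proposals return a sloped
penalty instead of an error, steering the optimizer back. Standard errors are
the square roots of the inverted negative Hessian's diagonal; a Hessian that
is not negative definite marks the fit inadmissible. Standard errors ignore
step-1/step-2 weight uncertainty — a known limitation of score-based
pipelines; bootstrap propagation is out of scope.

Standardization scales each linear coefficient by SD(predictor)/SD(outcome)
and the interaction by SD(X)·SD(score)/SD(outcome construct), with the
predictor SD fixed at 1 by the scale constraint, the score SD taken
empirically, and the outcome SD from the model-implied unconditional variance
`Var(Y) = b² + c²·Var(M) + 2abc + d²(Var(M) + a²) + Var(ζ_Y)` with
`Var(M) = a² + Var(ζ_M)` (a bivariate-normal product-moment identity). At the
population values this map is the identity, which is tested exactly.

## The synthetic population

`make_population()` assembles the standardized validation population: a
latent predictor with three indicators (loadings 0.7), a three-component
composite mediator, a latent outcome with loadings (0.7, 0.8, 0.9), and
structural coefficients `a = 0.4, b = 0.3, c = 0.4, d = 0.2` with the product
term mean-centered. Two weight sets are built in: (0.2, 0.4, 0.6) with all
component correlations 0.5, and (0.4, 0.5, 0.5) with correlations (0.25,
0.4, 0.16); both give the composite unit variance without rescaling. The
components are tied to the predictor by the cross-covariance rule
`Cov(m, X) = 0.4·Σ_mm w`, which makes the composite carry *all* covariance
between its components and the rest of the system — the defining property of
a composite model — and implies `Cov(X, M) = 0.4` for **both** weight sets.
All error variances are solved analytically for unit observable and construct
variances (`Var(ζ_M) = 0.84`, `Var(ζ_Y) = 0.6076`); nothing is calibrated by
simulation. The mediator residual is implicit (`M − 0.4X`), not drawn: the
generator draws the exogenous vector (predictor, components, measurement
errors, outcome disturbance) from one multivariate normal and builds the
endogenous variables deterministically.

Two published summaries of this design do not survive the algebra: the
reported mediator R² pair (0.12 vs 0.16 across weight sets) contradicts
`Cov(X, M) = 0.4` for both sets, which forces R²_M = 0.16 twice (and
R²_Y = 0.3924 for both); and the claimed interaction effect size f² ≈ 0.07
comes with no stated formula. `analytic_moments()` reports the derived
values; neither number is forced.

What the generator does **not** emulate: non-normal exogenous distributions
(the estimator leans on the normality of the latent predictor), measurement
error in the components, other moderated mediation topologies, and
misspecified measurement structures. Passing tests therefore speak to the
estimator's behavior under a correctly specified normal population, not to
its robustness.

## Monte Carlo protocol and numerical conventions

`run_condition()` repeats generate → CCFA → admissibility → weights/scores →
LMS → admissibility → standardize → moderation test until the target number
of admissible replications is reached; every draw is recorded, and the
inadmissibility share is inadmissible/(inadmissible + target). Per-draw seeds
are derived from the condition's master seed by a fixed integer mix, so a
redraw after an inadmissible fit is reproducible regardless of execution
order. A failure rate above 50% over the first hundred draws aborts with a
diagnostic (misconfiguration guard).

Admissibility is the standard SEM simulation screen, declared explicitly
because the criteria behind the published shares are not fully specified:
non-convergence, any negative variance estimate, a non-positive-definite
implied covariance, or a numerically singular composite loading matrix.
Whether repeated redraws enter the share denominator more than once is
likewise unstated in the source protocol; here every draw counts once.

Bias is `mean(θ̂) − θ`. The variance of the replications is taken about the
replication **mean** with divisor R − 1, and MSE = bias² + variance — the
display formula that sums squared deviations from the population value
double-counts the bias under that identity, so it is available only as the
`variance_about = "truth"` variant for exact-text replication; at the
near-zero bias levels of this design the two are indistinguishable.

The test suite runs the scaled-down protocol — 150 admissible replications
per condition with doubled tolerances — and 500 replications for the
type-I-error check (no-interaction population, n = 1000, nominal 5% two-sided
test); `scripts/acceptance.R` uses the same sizes. Single-fit consistency
checks use n = 30,000 (structural recovery within 0.02) and n = 10⁶ (sample
covariance vs analytic moments, CCFA loading recovery within 0.01). These
sizes are the package's chosen trade-off between Monte Carlo error and wall
time; the full 500-replication study is one `run_study(reps = 500)` call.

## Known limitations

* Standard errors do not propagate weight-estimation uncertainty from steps
  1–2.
* No overall model-fit statistic is reported for the interaction model; the
  marginal likelihood's mixture form does not admit the usual chi-square
  machinery.
* Components are assumed measured without error.
* One composite, one nonlinear latent dimension: latent-by-latent
  interactions and multiple composites sharing components are out of scope.
* Missing data are rejected rather than handled.
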