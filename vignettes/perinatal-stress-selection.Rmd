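---
title: "Selecting pregnancy-stress predictors of postpartum symptoms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting pregnancy-stress predictors of postpartum symptoms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery:
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data tests do and do not establish.

## 1. The analysis model

Each woman $i$ contributes an ordinal stress score $x_{iw} \in \{0,\dots,6\}$
for gestational weeks $w = 15,\dots,41$, an ACEs count (0–10), and two
postpartum totals: EPDS (0–30) and STAI-state (20–80). From a *completed*
panel the 29 predictors are

* $M_i$ — the person mean over weeks 15–41,
* $SD_i$ — the person (sample, $n-1$) standard deviation,
* $d_{iw} = x_{iw} - M_i$ — 27 person-mean-centered weekly deviations.

Person-mean centering makes $d_{iw}$ a *within-person timing* signal: a
week's deviation is judged against the woman's own typical level, not the
cohort's. By construction $\sum_w d_{iw} = 0$ exactly, so the deviation
block has rank 26; the penalized fit handles this (section 4).

For one outcome $y$ the adaptive LASSO minimizes

$$ F(\beta) \;=\; \sum_{i=1}^N \bigl(y_i - \hat y_i\bigr)^2 \;+\;
   \lambda \sum_{j=1}^{29} w_j \lvert\beta_j\rvert, \qquad
   w_j = 1 / \lvert \hat\beta^{\text{init}}_j \rvert^{\gamma}, $$

with an unpenalized intercept. The adaptive weights serve two purposes:
they give the estimator its oracle selection behavior, and they absorb the
very different predictor scales ($M$ spans 0–6, $SD$ roughly 0–2.6, the
deviations a few units around 0). For that reason predictors are used on
their **original scale** — the printed objective is honored literally — and
a `standardize = TRUE` option exists only for sensitivity analyses.

Settings and defaults:

| parameter | default | meaning |
|---|---|---|
| `gamma` | 1 | weight exponent; 0 gives the plain LASSO |
| `init` | `"ridge"` | initial estimates; ridge is always finite (the deviation block is exactly rank-deficient, so OLS is unavailable on the full design) |
| `kappa` | $0.01 \cdot \overline{\operatorname{colSS}}$ | ridge penalty, 1% of the mean predictor sum of squares |
| `nlambda`, `lambda_min_ratio` | 100, $10^{-3}$ | geometric path from $\lambda_{\max}$ (smallest all-zero $\lambda$) |
| `nfolds` | 10 | CV folds (seeded shuffle) |
| `cv_rule` | `"min"` | $\lambda$ at minimum mean CV MSE; ties go to the larger (sparser) $\lambda$; `"1se"` available |
| `tol`, `maxit` | $10^{-7}$, $10^6$ | coordinate-descent convergence controls |

Penalty weights are estimated **once per analysis dataset** and reused in
every CV fold, mirroring how penalty factors are normally used with
`cv.glmnet()`; per-fold re-estimation would change what is being
cross-validated (the whole pipeline rather than $\lambda$ given weights).

## 2. Multiple imputation

Missing weekly values — intermittent non-response and all post-parturition
weeks — are completed by chained equations with proportional-odds
conditionals, $m = 21$ times by default:

1. initialize each missing cell with a draw from its week's observed
   marginal distribution;
2. for `n_burnin = 10` cycles, for each week with missingness: regress the
   observed values on the neighboring weeks within ±3 and on the person
   mean of originally-observed weeks; draw parameters from the asymptotic
   normal of the MLE; draw each missing cell from the implied category
   distribution.

Conventions worth stating because they are genuine choices:

* **Post-parturition weeks are imputed like any other missing cell.** The
  29-predictor design needs every woman on the full 15–41 grid; the
  completed trajectory after delivery is a modelling convention, not a
  claim about lived stress. The alternative (computing $M$/$SD$ on
  pre-parturition weeks only) would make the deviation block incompatible
  with a fixed 29-column design.
* **The predictor window (±3 plus person mean)** keeps the conditional
  models well-posed: all 26 other weeks as predictors would put $p$ near
  $n$ with heavily intercorrelated columns.
* **Parameter draws** (rather than plugging in the MLE) make the
  imputation approximately proper, so between-imputation variability is
  not artificially suppressed. Draws are taken in an unconstrained
  parameterization (first cutpoint plus log-gaps), so every drawn model
  has strictly ascending cutpoints.
* The proportional-odds fitter is written in-package (BFGS with analytic
  gradient) because the imputation loop needs a covariance matrix for the
  draws, a ridge-stabilized fallback under separation, and the $K = 2$
  boundary case (plain logistic); `MASS::polr` and `glm` serve as
  independent oracles in the tests, not as the implementation.

Outcomes are never imputed: women missing an outcome are dropped from that
outcome's models, matching the analysis design.

## 3. Pooling by selection frequency

With $m$ fits per model, a predictor's *selection count* is the number of
fits with $\beta_j \ne 0$; it is retained when the count reaches
$\lfloor m/2 \rfloor$ (10 of 21 — the published rule — scaling to 3 of 7
at $m = 7$). Pooled coefficients average over **all** $m$ fits including
zeros (`policy = "all"`), the literal reading of "averaged over the
imputed datasets"; `"selected_only"` is provided because the phrase is
ambiguous. Effect sizes are $b \cdot SD(x)/SD(y)$ with both SDs computed
within each analysis dataset and averaged across the $m$ datasets (which
dataset's SDs the original analysis used is unstated; averaging is the
symmetric choice). Women with missing ACEs counts contribute to the
full-sample models only.

## 4. Numerical choices in the solver

Cyclic coordinate descent with warm starts; update
$\beta_j \leftarrow S(\rho_j, \lambda w_j/2)/\sum_i x_{ij}^2$ with
$S$ the soft-threshold operator, iterating over the nonzero set between
full sweeps (the standard active-set strategy). Predictors with infinite
weight (zero initial estimate) are excluded a priori. Convergence is
declared when the largest absolute coefficient change in a full sweep
falls below `tol`; non-convergence at any $\lambda$ is an error naming the
$\lambda$ and sweep count, never a silent warm start from a bad point.

The exact collinearity of the deviation block means the objective is flat
along one direction at small $\lambda$; the penalty breaks the tie, but
coordinate descent moves slowly along such a direction, and CV-fold fits
on small subgroups occasionally need on the order of $10^6$ sweeps
(sweeps cost microseconds at these sizes, so the cap is generous rather
than expensive). We kept the coefficient-change criterion rather than a
fitted-value criterion precisely because selection patterns live in that
flat direction.

Correctness is pinned by three independent oracles in the test suite: the
closed-form soft-threshold solution on orthonormal designs, an exhaustive
sign-pattern least-squares oracle on $p = 3$ problems across the path
(all $3^3$ KKT systems solved directly), and OLS at $\lambda = 0$; plus
cross-checks against glmnet (with its penalty-factor rescaling and
$1/(2N)$ objective scaling accounted for) on the plain-LASSO route and
under null responses.

## 5. The synthetic cohort: what it emulates

`simulate_cohort()` generates, per woman: a latent level
$\mu_i \sim N(\mu_0, \sigma_\mu^2)$; a volatility multiplier
$v_i \sim \text{lognormal}$ (mean 1, sigma `ar_sd_person_sigma`); latent
weekly values $z_{iw} = \mu_i + v_i e_{iw}$ with $e_{iw}$ a stationary
AR(1) (lag-1 correlation `ar_rho`); and the ordinal score by cutting
$z_{iw}$ at fixed thresholds. Outcomes are built from the **latent**
person summaries (mean, SD, deviations of $z$), so recovery targets are
well defined: measurement coarsening (thresholding to 0–6) is kept
separate from the signal. Noise is added, then totals are rounded and
clipped to the instrument range. Parturition truncation, intermittent
missingness and one-third outcome attrition are applied by
`apply_missingness()`.

Default calibration targets the printed descriptives of the reference
cohort: mean person-mean stress 3.01 (SD 1.20) and mean within-person SD
1.41 (SD 0.37). At the defaults a simulated cohort of $n = 2000$
reproduces all four within a few hundredths (the acceptance script
recomputes them). The volatility multiplier exists because without it the
between-person spread of person-SDs is pure sampling noise (about 0.26),
whereas the reference cohort's 0.37 (range 0–2.6) reflects real
heterogeneity in stress volatility — the very quantity a fluctuation
effect acts on. `ar_rho = 0.5` is a free choice (no autocorrelation
statistic is published); it gives trajectories that are neither white
noise nor random walks.

What the generator does **not** emulate: informative missingness (all
missingness is MCAR given parturition), item-level EPDS/STAI responses,
gestational-age dating error, time trends in stress across pregnancy, and
any dependence of stress on ACEs group beyond the planted outcome
effects. Passing recovery tests therefore show that the pipeline recovers
effects under its own assumptions — not that those assumptions hold in
real cohorts.

## 6. The recovery study and its power

The acceptance recovery study uses the generator defaults as study
conditions: $n = 400$ (half high-ACEs), planted high-ACEs depressive
effects $b_M = 2$, $b_{SD} = 2$, $b_{dev20} = b_{dev26} = 1.5$, outcome
noise SD 5, 15% intermittent missingness, 10-fold CV, 10 replicates, with
$m = 7$ imputations (retention 3-of-7, the $\lfloor m/2 \rfloor$ rule) to
keep a single-CPU run in minutes.

Two facts about the procedure are visible in the results and worth
understanding rather than hiding:

* **Planted effects are recovered.** $M$, $dev20$, $dev26$ are retained
  essentially always; $SD$ — whose signal is $b_{SD}$ times a
  between-person spread of only ≈ 0.36 against noise SD 5 — sits near the
  80% boundary. Fluctuation effects are intrinsically the hardest of the
  three to detect at these sizes.
* **Null weekly deviations are falsely retained more often than a naive
  reading of the frequency rule suggests** (the acceptance script reports
  mean/max null retention across replicates). The CV-"min" rule tolerates
  predictors that reduce CV error negligibly, and because the $m$ imputed
  datasets share all observed cells, a null week that is chance-correlated
  with the outcome in a given cohort draw is selected *consistently*
  across imputations — selection frequency across imputations does not
  average away cohort-level sampling noise. The `"1se"` rule selects far
  sparser models by construction and would suppress most of these false
  selections, at the cost of weak signals like the fluctuation effect;
  `"min"` is the default because it matches the reference analysis.
  Interpreting retained weekly deviations therefore warrants the same
  caution in real data.

## 7. Problem sizes used by the tests

Unit tests run on cohorts of 25–150 participants (up to 2000 for
calibration and slope-recovery checks, where only closed-form summaries
are computed); imputation bias checks use $n = 600$ with 5 seeds; the
recovery study uses $n = 400 \times 10$ replicates at $m = 7$. These
sizes were chosen so the full suite exercises every code path at
realistic subgroup sizes while staying a matter of minutes on one CPU;
all thresholds asserted by the tests are stated in the tests themselves.

## 8. Known limitations

* Chained-equations imputation is approximate-Bayesian, not a joint
  model; with heavy missingness in adjacent weeks its conditionals can be
  fit on few rows (the ridge fallback then engages and is logged).
* No post-selection inference: the pipeline reports no p-values or
  intervals, matching the reference analysis; pooled coefficients are
  shrunken by the L1 penalty and should be read as selection-stage
  estimates, not unbiased effect estimates.
* The retention rule treats imputations as exchangeable votes; it has no
  formal error-rate guarantee (see section 6).
* EPDS/STAI totals are modelled as continuous outcomes in 0–30 / 20–80;
  floor effects at EPDS 0 are not modelled.
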