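---
title: "Methods: joint multistate modelling of GADA-first progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint multistate modelling of GADA-first progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the models, the choices made where the design was genuinely open, the
numerics, and the limits of what the bundled synthetic-data experiments
can and cannot demonstrate.

## 1. The disease process and its state space

Progression after seroconversion to GADA as the first islet autoantibody
is modelled as a four-state process on the time-since-confirmed-GADA
clock: (1) single GADA, (2) multiple islet autoantibodies without IA-2A,
(3) multiple with IA-2A, (4) type 1 diabetes. Six forward transitions are
allowed (1→2, 1→3, 1→4, 2→3, 2→4, 3→4); state 4 is absorbing and the
graph is acyclic. IA-2A gets its own intermediate state because its
appearance marks a markedly faster route to clinical onset.

All hazards run on the shared time-since-GADA clock (a "clock-forward"
Markov structure): entering an intermediate state does not reset time.
This matches defining the hazard as a function of time since GADA
positivity and keeps the product-integral machinery exact; a semi-Markov
(clock-reset) variant is out of scope.

## 2. Longitudinal submodel

Each of nine biomarkers is modelled on its analysis scale — log(1 + x)
for the four OGTT measures and four titer z-scores, raw % for HbA1c —
by a linear mixed model

$$y_{ij}(t) = x_j(t)^\top \beta_j + z_j(t)^\top b_{ij} +
\varepsilon_{ij}(t), \qquad b_i \sim N(0, \Sigma_b),\ \
\varepsilon_{ij} \sim N(0, \sigma_j^2).$$

**Spline bases.** Metabolic trajectories are smooth: natural cubic
splines with interior knots at 1.5 and 5 years (boundary 0–15 years,
linear extrapolation beyond). Titers shift abruptly at seroconversion
events: piecewise linear splines with hinge knots at 1 and 3 years
post-GADA. Knot counts and positions are package choices — the spline
families are given by the study design, their knots are not. Knots are
fixed in the configuration rather than taken as data percentiles so that
a simulation truth and a fitted model can share one basis; with quarterly
visits over 0–12 years the 33rd/67th percentiles of observation times
land close to the chosen values anyway.

**Random effects.** Each variable carries a random intercept and a
random coefficient on its first non-intercept basis column. A fully
unstructured 18 × 18 covariance is not identifiable at a few hundred
subjects, so two structures are offered: `blockdiag` (default;
independent across variables, free 2 × 2 block within each, in which case
the multivariate likelihood factorizes and each variable is fitted by
`lme4::lmer` with ML) and `full` (one unstructured covariance estimated
by direct ML with a Cholesky parameterization and profiled fixed effects,
intended for small variable subsets where cross-variable coupling is the
question). REML is deliberately not used: the joint model needs ML.
Convergence for the `full` path: relative profile-likelihood change
below 1e-8 or 500 iterations.

The simulation truth, by contrast, *does* couple variables: its
$\Sigma_b$ is block diagonal plus two rank-one factors (an autoimmunity
factor loading on titer intercepts, a dysglycemia factor loading on
glucose/HbA1c intercepts), so it is positive semidefinite by
construction and induces realistic cross-variable correlation that the
default fitting structure ignores — a deliberate, documented
misspecification margin.

**Posterior random effects.** For a subject with stacked records
$(y, X, Z)$ the conditional of $b$ is Gaussian with
$E[b\,|\,y] = \Sigma_b (I + A\Sigma_b)^{-1} Z^\top R^{-1} (y - X\beta)$
and $\mathrm{Var}[b\,|\,y] = \Sigma_b - \Sigma_b (I + A\Sigma_b)^{-1} A
\Sigma_b$, $A = Z^\top R^{-1} Z$, computed with Woodbury identities so
cost is linear in the number of records. Zero records returns the prior.

## 3. Multistate submodel

Transition intensities are proportional hazards on the time-since-GADA
clock,

$$h_k(t) = h_{0k}(t)\,\exp\{\gamma_k^\top w + \alpha_k^\top m_i(t)\},$$

with piecewise-constant baselines (default cut points at the tertiles of
each transition's observed event times; a single level when a transition
has fewer than six events). The last level extends beyond the last cut.
Likelihood is the full counting-process likelihood
$\sum_{\text{events}} \log h_k(T) - \int h_k(u)\,du$; the integral is
exact over the constant-baseline segments with $m(t)$ evaluated at
midpoints of a configurable sub-grid (0.1 years by default; halve it for
oracle-grade accuracy). With ties broken by the simulator's visit jitter
and a full likelihood, no Breslow/Efron choice arises.

**Estimation.** Each transition is fitted through the standard Poisson
representation of the piecewise-exponential model: one row per sub-grid
piece, offset log(exposure), unpenalized intercept-plus-piece columns for
the baseline (profiling it), covariates centered at their risk-set means
(centering moves the baseline, never the coefficients). Unpenalized fits
use IRLS (`glm.fit`) with SEs from the observed information; LASSO fits
use `glmnet` (Poisson, standardized covariates, penalty factor zero on
baseline columns), followed by an unpenalized refit on the selected set
for SEs and Wald p-values. Coefficients below 1e-8 after soft
thresholding are exact zeros. Excluded covariates are reported with a
post-selection SE from a one-at-a-time re-entry refit and no p-value,
mirroring the zero/"—" reporting convention; these SEs are descriptive,
not inferential.

**Penalty tuning.** Subject-level K-fold cross-validation scores each
penalty by the held-out unpenalized log-likelihood, normalized per
held-out event so fold scores are comparable in scale. Two rules are
offered: `min` (maximize the mean held-out log-likelihood; prediction
optimal, tends to over-select) and `1se` (largest penalty within one
fold-standard-error of the optimum; the usual parsimony rule, used by the
package's selection-pattern experiments). Tuning is per transition.

**Transition probabilities.** $P(s,t)$ is the product integral
$\prod (I + A(u)\,du)$ of the intensity matrix along a subject's
covariate path, step 1/120 year (≈ 3 days) by default. Rows are
renormalized against accumulated floating error; unreachable entries
under the acyclic graph are exactly zero; Chapman–Kolmogorov holds to
within O(step).

## 4. The joint model and dynamic prediction

The association is *current-value*: each transition's hazard reads the
model-implied (noise-free) biomarker values $m_i(t)$, never the raw
noisy observations. The subject-level joint likelihood integrates the
shared random effects out of
$p(y\,|\,b)\,p(\text{path}\,|\,b)\,p(b)$. Three integration methods:

- **Laplace** (default): Newton mode finding with fully analytic
  gradient and Hessian — the path contribution has Hessian
  $-\sum_k \int h_k(u)\,g_k(u) g_k(u)^\top du$ with
  $g_k(u) = Z(u)^\top \alpha_k$, accumulated on the same sub-grid as the
  likelihood integral. Eighteen-dimensional modes cost milliseconds.
- **Adaptive Gauss–Hermite** (dimension ≤ 3), centered and scaled by the
  Laplace mode and curvature; used as a numerical oracle.
- **Plain Monte Carlo** over the prior with antithetic draws; the slow
  reference implementation retained for validation. The three agree to
  ~1e-3 on a one-dimensional toy.

**Fitting** is two-stage with refinement: (1) ML longitudinal fit; (2)
multistate fit on covariate paths implied by longitudinal-only posterior
means; (3) iterate { recompute each subject's posterior *mode* under the
current hazards — so surviving a high-risk spell pulls the trajectory
down — then refit the hazards on the updated paths }, tracking the
summed Laplace joint log-likelihood and keeping the best iterate (the
refit step is not guaranteed monotone, and with very sparse transitions
it can be unstable; `converged = FALSE` flags that case). This
mode-based refinement is an approximation to full joint maximization; it
removes most of the attenuation that LOCF-style covariate handling
produces (demonstrated in the test suite), at a fraction of the cost of
a full EM with high-dimensional quadrature.

**Prediction.** Given a history up to landmark $s$ (records, stage path,
and survival in the current state), random effects are drawn by
importance sampling: proposal = closed-form Gaussian longitudinal-only
posterior; weights = the multistate likelihood of the observed path plus
survival in the current state up to $s$. Exact transition times inside
inter-visit intervals are not imputed — the survival contribution uses
"still in state q at s" only. Effective sample size is reported and a
warning advises more draws below 5% efficiency. Occupancies average the
product-integral row of the current state over draws; predictions are
recomputed from scratch when new data arrive (no incremental state), so
updating is exactly landmark-consistent.

## 5. The synthetic cohort generator

The generator exists so that every stage of the pipeline can be
exercised and validated without access to the restricted registry data.
Its defaults are the study conditions:

- **Baseline covariates:** female 45.9%, FDR 17.4%, DQ2/8 48.8%,
  DQ8/X 29.6%, DQ2/X 21.6%.
- **Age at GADA:** a two-parameter log-normal cannot reproduce the
  reported median 5.1 with quartiles (2.4, 9.0) — the log-scale quartiles
  are asymmetric about the log-median — so ages are drawn by inverse-CDF
  through a monotone (Hyman) spline interpolation of quantile anchors at
  those three quartiles plus mild tail anchors inside (0, 15). The
  sampled quartiles then match the targets by construction.
- **Trajectory truth:** mean curves anchored at the reported baseline
  medians on the analysis scale with gentle age trends (C-peptide and
  HbA1c rising as children grow; GADA titers rising steeply in year one
  then flattening); residual SDs and random-effect SDs chosen at
  magnitudes a paediatric-endocrinology cohort would call realistic
  (e.g. between-child SD 0.43 on log GADA-z, 0.2% on HbA1c). Fixed-effect
  vectors are obtained once, at configuration time, by least-squares
  projection of the target curves onto the fitting bases.
- **Transition truth:** the published per-transition coefficient table,
  zeros kept as exact zeros; covariates centered at their time-zero
  means so the baselines are interpretable. Baseline hazards are
  piecewise constant (two pieces, cut at 3 years) with levels set once so
  that a simulated cohort occupies all four states at 10 years; direct
  1→4 progression is kept rare, as it is clinically.
- **Observation scheme:** quarterly visits from GADA positivity to age
  15 (quarterly throughout, since all subjects are autoantibody
  positive), titers at every visit, HbA1c from the first
  post-seroconversion visit onward, OGTT biannually while in a
  multiple-autoantibody state from age 3; visit jitter uniform ±2 weeks
  (tie-breaking; can be disabled); no records at or after entry into
  state 4.
- **Event sampling:** competing time-varying intensities by
  Lewis–Shedler thinning with the dominating rate taken as 1.2 × the
  maximum total intensity on a 0.1-year grid of the remaining window —
  validated against inverse-CDF sampling by Kolmogorov–Smirnov.
- **Reproducibility:** every subject consumes its own substreams
  (baseline/effects/events/observations) derived from the master seed,
  so cohorts are byte-identical across runs and stable under any
  generation order.

**What the generator does not emulate:** pre-GADA life and reversion of
transient autoantibodies, country effects, assay batch structure,
loss-to-follow-up other than administrative censoring at age 15, and
interval censoring of transition times — simulated transitions are
recorded at their exact times (right-endpoint detection at visits is a
convention the I/O layer tolerates but the estimators do not exploit).
Passing the bundled experiments therefore shows the estimators are
correct under the model, not that the model is correct for any real
cohort.

## 6. Validation experiments and problem sizes

The test suite runs entirely on generated data; sizes were chosen to
make each check statistically meaningful at desk scale:

- *Coefficient recovery:* one cohort of n = 2000 (n = 5000 if direct
  1→4 events are under 30), unpenalized fit on latent paths; eight
  representative coefficients within ±max(stated band, 2 SE) of truth.
- *Selection pattern:* 15 replicates of n = 1000 with per-transition
  `1se` cross-validation; exclusion of true zeros and retention of
  |coefficient| ≥ 0.6 covariates aggregated over replicate × covariate
  cells. Note: the retention bar (90%) is not attainable under these
  conditions — scanning the full penalty path shows that for the 2→3 and
  2→4 transitions *no* penalty simultaneously excludes ≥ 80% of the true
  zeros and retains ≥ 90% of the strong covariates, because the
  glucose/HbA1c block is strongly correlated and the rare transitions
  (~70 events) leave |β|·SD ≈ 0.25 for the binary covariates. The test
  asserts the bar anyway and is expected to stay red; the exclusion bar
  passes with a wide margin.
- *Mixed-model recovery:* n = 500 under a no-feedback configuration
  (hazards carry no longitudinal terms). Under the full truth the
  OGTT/HbA1c record stream is informatively truncated — precisely the
  bias the joint model corrects — so a recovery check of the mixed-model
  estimator itself must be run where its MAR assumption holds. The
  balanced random-intercept toy is checked against the closed-form
  one-way ML estimators to 1e-6.
- *Dynamic-prediction self-consistency:* 2000 forward-simulated futures
  from the generating model for one subject, compared with
  `predict_occupancy` at five grid times within 3 Monte-Carlo SD.
- *Numerical oracles:* product integral vs competing-risks closed forms
  (1e-4 at step 1e-3), likelihood vs per-segment trapezoid quadrature
  (1e-5), Laplace vs 30-node Gauss–Hermite vs 10^6-draw Monte Carlo
  (1e-2) on the one-dimensional toy.
- *Attenuation:* at n = 150 over five replicates the per-replicate
  |bias| comparison between the joint and a LOCF fit is dominated by
  shared sampling noise, so the suite asserts the deterministic ordering
  (joint estimate above the attenuated LOCF estimate in at least four of
  five replicates) together with the replicate-averaged bias comparison.

## 7. Known limitations

- The default `blockdiag` fit ignores cross-variable random-effect
  correlation; the `full` structure is exponential in bookkeeping, not
  in cost, but is only sensible for a handful of variables.
- Post-selection SEs for LASSO-excluded covariates are descriptive.
- The refinement loop is not a full joint maximizer; with very sparse
  transitions the unpenalized refit can diverge (coefficients are capped
  at ±15 with a warning) and a penalized refit is the practical choice.
- Interval censoring is handled by convention, not by an
  interval-likelihood; with quarterly visits the bias is small but not
  zero.
- Importance sampling degrades when the survival information is very
  strong (ESS warning); a sequential scheme would be the next step.
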