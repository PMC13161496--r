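---
title: "Methods: mediation with a longitudinal mediator and an ordinal treatment-dependent confounder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a randomized lifestyle intervention with a time-to-event endpoint, part
of the treatment effect may be transmitted through a continuous biomarker
trajectory (here thought of as BMI on an analysis scale, centred at 25
kg/m2 and divided by 5). Behavioural changes induced by the same
intervention — summarised as an ordinal lifestyle score `L` with levels
0 < 1 < 2 — affect both the biomarker and the outcome, so `L` is a
*treatment-dependent confounder*: conditioning on it naively breaks the
identification of natural direct and indirect effects.

The package's estimands are contrasts of expected restricted event-free
time within `t_max = 15` years (the RMST scale, in years). Defining the
mediator as the *latent trajectory function* avoids conditioning on
post-treatment measurements and keeps the mediator finite-dimensional
through its random-effects representation.

## Identification and the sensitivity parameter

With a trichotomous `L`, monotonicity (the intervention never lowers the
lifestyle score) forces the joint distribution of the counterfactual pair
`(L_a*, L_a)` in each baseline-covariate stratum to be upper triangular.
Its margins are identified by the multinomial model; one degree of freedom
remains, taken as `p11 = P(L_a* = 1, L_a = 1)`, constrained to
`[p_min, p_max] = [max(0, 1 − Φ3 − Φ4), min(Φ2, Φ5)]` and parameterised as
`p11 = p_min + ρ (p_max − p_min)` with `ρ ∈ [0, 1]` per stratum.
`p_min ≤ p_max` is a *necessary* condition for monotonicity, checkable from
data; the package reports the proportion of posterior draws violating it in
at least one stratum (`check_monotonicity`). Draw-level handling is
configurable: the default excludes infeasible draws from effect assembly
and reports the excluded fraction; a clipping alternative is available.
The stricter *step monotonicity* (at most a one-level increase) pins
`p11 = 1 − Φ3 − Φ4` and needs no sensitivity parameter, but can be
inconsistent with the fitted margins; its validity is also reported.

Because every effect component is linear in the coupling entries, any
functional of the coupling is affine in `ρ`, so stratum-wise extremes of
the direct and indirect effects are attained at `ρ ∈ {0, 1}`
(`rho_extremes`). Dropping monotonicity altogether, sharp bounds for any
linear functional are computed by linear programming over the
transportation polytope of couplings with the given margins
(`partial_id_bounds`); the monotone range is always contained in these
assumption-free bounds. For a `K`-level confounder,
`k_level_monotone_joint` generalises the construction with a
`(K−1)(K−2)/2`-dimensional sensitivity vector filled by sequential
interval scaling (each free interior cell is scaled into its currently
admissible interval, computed by LP, starting from the `(1,1)` cell and
moving outward row by row); `K = 2` is fully identified and `K = 3`
reproduces the single-`ρ` construction. The sequential-scaling order is a
package convention; only margin and structural correctness are guaranteed
for `K > 3`.

## Parametric models

* Trajectory: natural cubic splines, population basis with boundary knots
  {0, 10} years and inner knots {1, 3, 5}; random-effect basis with inner
  knots {1, 5}. Both bases are anchored to zero at `t = 0`, so the
  intercept is the baseline value; beyond the upper boundary knot the
  bases extrapolate linearly (exit times can exceed 10 years).
* Survival: piecewise-constant baseline hazards per arm with default cuts
  at {2, 4, 6, 9, 12} years on a 15-year horizon (chosen to give roughly
  even event counts under incidence of the order seen in diabetes
  prevention cohorts; configurable). Two trajectory functionals are
  implemented: the three-year legacy integral (constant in time, making
  the hazard piecewise-constant and all survival integrals closed-form)
  and current change (evaluated by Gauss–Legendre quadrature with 15
  nodes per piece, for both the cumulative hazard and the RMST outer
  integral).
* Confounder: multinomial logit with reference level 0; covariates one-hot
  encoded with first level as reference. Variants add
  treatment-by-covariate interactions; PSIS-LOO (implemented in-package
  with the Zhang–Stephens generalized-Pareto tail fit) compares variants,
  preferring the most parsimonious model unless a richer one wins by more
  than 2 standard errors of the difference — the threshold is a package
  convention.

Priors follow a single protocol: N(0, 5) for every regression coefficient
(the mediator is centred and scaled so larger effects are implausible),
Gamma(0.5, 0.5) per baseline-hazard piece, half-Cauchy(0, 10) for the
residual and random-effect SDs, and LKJ with shape 2 (mild regularisation;
the shape is configurable) on the random-effect correlation matrix.

## Posterior computation

The joint posterior is sampled by a blocked Metropolis-within-Gibbs scheme
designed around the model's conditional structure:

* trajectory fixed effects are proposed from their exact Gaussian
  conditional given the longitudinal data (pCN-damped when acceptance
  drops) and corrected by the survival factor with the baseline hazard
  integrated out analytically (Gamma conjugacy), which removes the
  coefficient–baseline coupling;
* per-subject random effects are proposed from their Gaussian
  longitudinal conditional (vectorised 4×4 Cholesky across subjects) and
  accepted per subject on the survival ratio;
* baseline-hazard pieces are exact Gamma draws;
* the residual SD uses its inverse-gamma conditional with a correction to
  the half-Cauchy prior;
* the random-effect covariance combines an inverse-Wishart conditional
  proposal (corrected to the half-Cauchy + LKJ target) with a marginal
  move in (log-SD, atanh-correlation) coordinates in which the random
  effects are integrated out of the longitudinal factor and redrawn;
* survival coefficients use adaptive random-walk Metropolis on the
  collapsed target, preconditioned by a Laplace fit at initialisation;
* interweaving moves break the centred-parameterisation funnels: shifts
  of subject-constant coefficients compensated through the random
  intercept, exact Gibbs shifts between the population spline
  coefficients and the random-effect spline coefficients (the
  random-effect spline space is nested in the population space, so the
  compensation is exact and both likelihood factors are invariant), and
  joint rescaling/correlation moves for the covariance (ASIS).

Split-chain R-hat is reported for every population parameter; the default
protocol is 4 chains × (2000 warmup + 2000 sampling) and a `thin` argument
trades extra iterations per stored draw. Reduced protocols used in the
package's tests (2 chains × (500 + 500), `thin` 3 to 4) reach max R-hat
around 1.02-1.07 on study-sized data.

## Effect assembly

For each posterior draw (paired with a confounder-model draw), the five
components `DE(r)`, `IE(r)`, `ΔDE`, `ΔIE` and `δ` are evaluated by exact
summation over the observed covariate strata (weighted by their pooled
empirical frequencies — treatment is randomised) and the confounder
levels, and Monte Carlo integration over the random effects with atoms
shared across every scenario within a draw (default 100 atoms; the shared
atoms remove between-scenario Monte Carlo noise from the contrasts). The
four-term decomposition of the expected outcome uses reference level
`l† = 0` and a flat reference trajectory equal to the profile's baseline
value, which makes the trajectory functional vanish; the assembled `DE`,
`IE` are contrasts and do not depend on this choice (verified by test).
The conditioning convention follows the parametric formulae that carry the
shared random intercept inside every beta term and integrate over the full
random-effects law; a marginal-convention variant would integrate `r0` out
of the level and reference terms first — the two agree after the outer
integration, and the package implements the former.

For the legacy functional all RMST evaluations are closed-form piecewise
exponential integrals, vectorised across strata × atoms × scenarios; for
current change the survival curves are integrated on a uniform 241-point
grid by the trapezoid rule (about 1/16 year spacing; the scalar `rmst`
function uses nested Gauss–Legendre quadrature instead and serves as the
accuracy reference).

## The synthetic-data generator

`generate_dataset` simulates from exactly the structural model above:
covariates from independent category margins (3 age × 2 sex × 3 smoking ×
3 baseline-score levels, 54 strata), fair randomisation, the counterfactual
confounder pair from per-stratum monotone couplings built at `ρ = 0.5`
from a multinomial-logit truth, random effects, latent trajectories,
noisy annual visits to year 10 (±0.1-year jitter) truncated at the exit
time, and event times by exact inversion of the cumulative hazard with
administrative censoring at 15 years and no other dropout. Shared uniform
draws across the four (treatment, mediator-world) combinations give
per-subject cross-world contrasts, so `DE + IE = TE` holds exactly subject
by subject and `true_effects` returns Monte Carlo oracles with standard
errors. The generator's default parameters are small-magnitude values
chosen to emulate a diabetes-prevention cohort — a one-BMI-unit
intervention dip over the first three years that rebounds, roughly half
the cohort experiencing the event in 15 years, and a total effect of
about 1.6 event-free years (oracle TE 1.65, DE 0.91, IE 0.74) — they are
the package's own test bed, not estimates from any real study.

What the generator does *not* emulate: informative dropout and death
(censoring is purely administrative), measurement of the raw lifestyle
components (the trichotomous score is drawn directly), visit-process
dependence on health status, or model misspecification of any kind.
Passing recovery tests therefore demonstrates internal consistency of
estimator and generator, not robustness to the ways real cohort data
deviate from the model.

## Numerical choices and limitations

* Feasibility tolerance for monotone couplings is 1e-9 (posterior draws
  are floating point); tiny negative cells from round-off are clamped.
* The legacy integral is exact Gauss–Legendre per inter-knot segment
  (cubic integrands); dual closed-form/quadrature paths of the cumulative
  hazard agree to 1e-8 and are both exposed for checking.
* Event-time simulation inverts the piecewise-linear cumulative hazard
  exactly; a thinning sampler with a grid-derived dominating constant
  covers non-constant hazards and doubles as a self-consistency check.
* Ties in the lifestyle-score categorisation go to the lower category.
* Identification of the trajectory-functional coefficients `ζ` rests on
  within-cell variation of the functional, which is latent and inferred
  from the visit history; in small samples (a few hundred subjects) their
  posterior — and hence the DE/IE split — can remain diffuse even when
  the total effect is sharply estimated. Recovery experiments show
  reliable coverage from roughly 500 subjects upward, consistent with the
  sample sizes at which estimation is typically considered satisfactory
  for designs of this kind.
* Problem sizes in the test suite (replicate counts, chain lengths,
  Monte Carlo sizes) are scaled-down smoke versions of the full
  experiments; the full protocol is a matter of setting `chains`,
  `warmup`, `sampling` and `n_re_atoms` in `analysis_config`.
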