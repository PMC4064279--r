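---
title: "Planning daily psychological-state injury studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning daily psychological-state injury studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injurydesign)
```

## The design problem

Day-to-day psychological states — confidence, anxiety, mood, soreness,
sleep — are plausible short-horizon risk factors for performance
injuries in athletes and performing artists. Studying them prospectively
means collecting a short ordinal questionnaire every day from every
roster member and relating each day's state to whether an injury
occurred at that day's performance. Two statistical facts make such
studies hard to size:

1. **Injuries are rare.** Time-loss injuries (at least one missed
   performance) occur at roughly 1.5–1.6 per 1000 artist-exposures in
   nightly-show companies; medical-attention injuries (anything reported
   to a show therapist) at roughly 10 per 1000. Information accrues with
   the number of *events*, not person-days.
2. **Daily states are sticky.** The intraclass correlation (ICC) — the
   share of a state's variance attributable to stable between-person
   differences — ranged from 0.16 (illness in the past 24 h) to 0.58
   (confidence) across the nine daily items of the pilot panel that
   motivates this package (`daily_state_iccs()`). The higher the ICC,
   the less new information each extra day of measurement contributes.

The package provides the four computations a design team needs, plus a
synthetic data generator so every computation is testable without access
to any raw cohort:

* Monte-Carlo power for the *prospective cohort* analysed with marginal
  (GEE-type) or mixed-effects logistic models (`estimate_power()`,
  `power_grid()`);
* closed-form sample size for the *prospective nested case-crossover*
  design, i.e. an m:1 matched case-control problem with correlated
  dichotomous exposure (`matched_design()`, `required_cases()`);
* study-duration arithmetic converting required cases into
  artist-performances and months of follow-up (`plan_study()`,
  `plan_scenarios()`);
* injury-surveillance descriptives (`classify_injuries()`,
  `injury_rate()`, `recruitment_rate()`).

## The synthetic panel generator

No raw daily-state panel is distributed, so the generator *is* the
package's data substrate. Its model is deliberately the simplest one
matching the two printed constraints of the motivating cohort — the
per-variable ICCs and the 7-point ordinal scale:

For participant $i$, day $d$ and variable $v$, a latent Gaussian state

$$z_{ivd} = b_{iv} + e_{ivd}, \qquad
  b_{iv} \sim N(0, \rho_v), \quad e_{ivd} \sim N(0, 1 - \rho_v)$$

has exchangeable (compound-symmetry) day-to-day correlation exactly
$\rho_v$, the target ICC. The latent value is discretised into $K$
categories (default $K = 7$) through the equiprobable standard-normal
cutpoints $\Phi^{-1}(k/K)$, which preserves ranks and gives a uniform
marginal over categories. Missingness is injected completely at random
(default 4%, matching the pilot's per-item nonresponse of roughly 3–5%).

Injuries are independent Bernoulli draws per participant-day (one
performance per day, so participant-days are artist-exposures), with

$$p(s) = \min\!\Big(1,\ \frac{\lambda_0}{1000}\,
  \theta^{(s - \bar s)/2}\Big),$$

where $\lambda_0$ is the baseline rate per 1000 exposures (default 1.6),
$\theta$ the rate ratio per 2-category state change (default 1.25, the
minimal important difference), $s$ the day's state and $\bar s$ the
scale midpoint. Centering at the midpoint keeps the marginal rate at
baseline under the null. Days with a missing state are exposed at
baseline. One third of injuries (the pilot's 3 of 9) additionally cause
missed performances and are classified time-loss.

**What the generator does *not* emulate** — and hence what passing
tests cannot show about real panels: inter-item correlation across the
nine variables (they are generated independently); any weekly/daily
questionnaire alternation; non-uniform ordinal marginals (real daily
states concentrate near "normal" rather than spreading uniformly over
the scale); informative missingness; and within-person autocorrelation
beyond compound symmetry (no AR(1) decay). The uniform marginal is the
maximum-variance case for a $K$-point scale, a point that matters for
power (below).

All randomness flows from one root seed through fixed per-stream
derived seeds, so states and injuries are independently reproducible
and identical configurations give bit-identical output.

## ICC estimation

`estimate_icc()` implements the one-way random-effects ANOVA estimator

$$\widehat{ICC} = \frac{MS_B - MS_W}{MS_B + (k_0 - 1) MS_W},
  \qquad k_0 = \frac{N - \sum_i k_i^2/N}{n - 1},$$

with $k_0$ the standard unbalanced-design effective group size (equal
to the common group size when the panel is complete). Ordinal scores
are treated as numeric. This is the textbook choice; no model-based
(REML) variant, ICC(2,1)/ICC(3,1) forms, or confidence intervals are
offered. Zero within-participant variance returns 1 with a
`degenerate` flag (observed in the pilot, where three artists never
varied on some items); negative ANOVA estimates are reported as
computed with a `negative` flag, truncation being an explicit option,
because a truncated value would silently change downstream power
inputs. On generated panels the estimator recovers the latent target
within ±0.05 at the planned-cohort scale of 210 × 100 (asserted by the
tests); estimates computed on the 7-point *scores* are additionally
attenuated by the discretisation — by the squared correlation between
category scores and the latent variable, $\lambda^2 \approx 0.918$
for seven equiprobable categories — which matters when feeding
score-based ICCs back into the matched design as exposure
correlations.

## Power simulation for the prospective cohort

`estimate_power()` chains the generator and `fit_injury_model()` over
replicates and counts two-sided Wald rejections. Two engines:

* **marginal** — binomial-logit GEE with exchangeable working
  correlation, clustered by participant, robust sandwich errors. No GEE
  fitter ships with the environment's core packages, so the estimating
  equations are solved in-package by Fisher scoring, using the
  closed-form exchangeable inverse ($R^{-1} = c_1 I + c_2 J$) so each
  iteration is linear in the number of observations. The implementation
  is verified in the tests against ordinary logistic regression (to
  which it reduces exactly under the independence working correlation)
  and against an independent clustered-sandwich oracle.
* **mixed** — binomial-logit random-intercept model via `lme4::glmer()`.
  The default `nAGQ = 0` approximation is used for simulation
  throughput; a `mixed_type = "linear"` variant (linear-probability
  mixed model) is kept behind a flag as a literal-minded alternative
  reading of "linear mixed models" for a binary outcome.

Replicates with no events have no test statistic; they are excluded
from the power denominator and counted in `n_failed_fits` (more than
20% flags the estimate unreliable). At the null the rejection rate of
both engines is calibrated to $\alpha$ within Monte-Carlo error, which
the tests assert; the robust-variance Wald test is mildly
anticonservative with tens of events, a known small-sample property we
deliberately do not correct because the planned analysis (standard GEE
software) would share it.

**Sensitivity to the ordinal marginal.** Because the generator's
equiprobable cutpoints give the uniform (maximum-variance) marginal,
the exposure variance per category — hence the simulated power at a
fixed rate ratio — is at the top of the plausible range. Simulations
calibrated by resampling a real, centre-heavy panel would see smaller
effective exposure variance and correspondingly lower power at the same
nominal effect. Power figures from this generator at the reference
scenario (180 artists × 100 days, 1.6/1000, rate ratio 1.25, ICC 0.35)
should therefore be read as optimistic for that scenario, and the
qualitative conclusion — a purely prospective daily-measurement study
of time-loss injuries is infeasible at achievable rosters — is reached
*a fortiori*. The full published grid (up to 1000 artists × 250 days)
is not re-run by the default test suite; the suite asserts the
monotone structure (power non-decreasing in artists, days, and effect)
on small scenarios and leaves full-scale grids to `power_grid()` as a
long-running job.

## The matched case-crossover sample size

The planned rescue design measures artists once or twice weekly and
again post-injury: each injured artist contributes one matched set —
the injury performance plus $m = 10$ referent observations of the same
person — making the within-set exposure correlation $\phi$ equal to the
state's day-to-day ICC. Parameters: control exposure probability
$p_0 = 0.3$ (state dichotomised at "2 or more categories adverse"),
exposure odds ratio $\psi$ (1.25 or 1.5), $\alpha = 0.05$ two-sided,
target power 0.8.

`required_cases()` implements the classic correlated matched
case-control calculation (the PS/Dupont lineage — the standard tool
taking exactly this four-parameter set). Writing
$p_1 = \psi p_0 / (1 + p_0(\psi - 1))$ for the case-occasion exposure
probability, the $m$ referent observations are conditionally
independent given the case occasion, exposed with probability
$p_0 \pm \phi\sqrt{p_1 q_1 p_0 q_0}/p_1$ (resp. $/q_1$). The test whose
power is approximated is the conditional score test: a set with $t$ of
its $m + 1$ occasions exposed contributes $y - t/(m+1)$ ($y$ = case
occasion exposed), with null conditional variance
$t(m+1-t)/(m+1)^2$; under the alternative
$P(y = 1 \mid t) = \psi t / (\psi t + m + 1 - t)$. A normal
approximation of the standardised sum over sets gives the achieved
power, inverted to the smallest integer case count.

Three design choices deserve record:

* **Formulation.** Two other natural formulations were evaluated
  against the reference planning table (required cases 828–1301 as
  $\phi$ runs from 0.16 to 0.58 at $\psi = 1.25$). A fully exchangeable
  set model (beta-binomial exposure totals with the same conditional
  tilt) overshoots the table increasingly with $\phi$, by up to 45%;
  a marginal-odds-ratio model in which $\phi$ only perturbs the joint
  exposure distribution produces the *wrong monotonicity* (required
  cases decreasing in $\phi$), because holding the marginal odds ratio
  fixed while correlating exposures inflates the within-set
  conditional odds ratio. The formulation above reproduces all nine
  reference rows to within 0.31% (residuals −1, −1, −1, −1, 0, 0, +1,
  +3, +4 cases), preserves strict monotonicity in $\phi$, and yields
  the documented ~30% requirement at $\psi = 1.5$; we adopt it as this
  package's method.
* **Continuity correction.** Available (`continuity_correction =
  TRUE`) but off by default: the corrected approximation no longer
  reproduces the reference table (it raises every requirement beyond
  the table's reproduction band), the uncorrected one does.
* **Rounding.** The case requirement is the ceiling integer and the
  achieved power at that integer is always reported alongside.

`simulate_matched_power()` is the independent check of the normal
approximation: it simulates the same probability model at the set
level (exposure totals from the correlated distribution, case occasion
assigned by the conditional odds) and applies the conditional score
test per replicate study. At $\phi = 0$ this sampling scheme provably
coincides with drawing every occasion's exposure independently, which
the tests exploit as a second, member-level oracle. Agreement is
within 2 percentage points across $\phi \in [0, 0.6]$ at 10,000
replicate studies.

## Study-duration planning

Deterministic arithmetic, kept exact and dimension-consistent:
performances $= \text{cases} / (\text{rate}/1000)$; months
$= \text{performances} / (\text{roster} \times \text{performances per
artist-year}) \times 12$. Defaults: 210 artists (35 per show on six
shows) and 470 performances per artist-year. Months are reported raw
and rounded half-up to the nearest integer, the convention that
reproduces all six published horizon figures (67, 105, 20, 32, 10, 16
months) from their case counts. One chained figure differs by one
month from the published narrative: at $\psi = 1.25$, $\phi = 0.58$,
rate 10/1000, the method's own 1305 cases give 130,500 performances
and 16 months (the published 1301 → 130,100 also gives 16; at the
time-loss rate of 1.5/1000, 1305 gives 106 months where the published
1301 gives 105). The planner is therefore tested both ways: exactly on
published case counts, and at its own chained values.

## Descriptives

`classify_injuries()` enforces the surveillance hierarchy
(medical-attention ⊇ time-loss), rejects records classified time-loss
with no missed performances, and excludes personal (non-work) health
conditions flagged in the log. Rates per 1000 artist-performances and
recruitment percentages are rounded half-up to one decimal — the
convention matching every published figure, including the two distinct
recruitment baselines kept as worked examples (37/82 = 45.1% of those
approached; 36/82 = 43.9% counting the pre-study withdrawals
differently).

## Numerical choices and degenerate inputs

* Seeds are 32-bit-safe; every user-facing stochastic function takes an
  explicit seed and restores the caller's RNG state.
* GEE convergence: max |Δβ| < 1e−8, 50 iterations; the working
  correlation is clamped to its positive-definite range; |β| > 30 is
  declared separation. Failures are *reported*, never silently dropped.
* `required_cases()` brackets by doubling and solves by `uniroot` at
  tolerance 1e−9, then verifies the integer; an unreachable target
  (e.g. $\psi = 1$) raises an explicit error.
* Invalid matched designs ($p_0$, $\psi$, $\phi$ implying a joint
  exposure probability outside [0, 1]) are rejected at construction.
* Panels that are all-constant return `NA` ICC with a degenerate flag;
  empty grids, empty logs and zero-rate generators all return empty,
  correctly-typed results.

## Problem sizes used by the test suite

The default suite simulates at the scales that make each property
decidable rather than at full published scale: ICC recovery at
210 × 100 (the planned-cohort size), power calibration and
engine-comparison scenarios at 50–120 participants × 30–60 days with
elevated baseline rates (10–40 per 1000) so that event counts are
informative at a few hundred replicates, the reference power scenario
at its published 180 × 100 size with 500 replicates, and the matched
oracle at 10,000 replicate studies. These choices are the package's
own trade-off between Monte-Carlo resolution and turnaround.

## Known limitations

* The matched-design method is an approximation lineage, not an exact
  conditional power; its residual against the reference table (≤ 4
  cases in 1301) is documented above rather than tuned away.
* The generator's uniform ordinal marginal overstates exposure
  variance relative to centre-heavy real panels (see above); users
  calibrating to their own cohort should replace the equiprobable
  cutpoints with empirical ones before trusting absolute power levels.
* Variables are independent; multi-variable analyses (nine correlated
  states, multiplicity) are out of scope.
* The mixed engine's `nAGQ = 0` default trades likelihood accuracy for
  speed; slope Wald tests are insensitive to this at the event counts
  involved, but variance components should not be interpreted from it.
* No accrual, dropout, vacation-calendar or per-show heterogeneity
  modelling: the planner assumes a fixed roster performing year-round.
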