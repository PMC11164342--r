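---
title: "Modelling CA-125 treatment-response dynamics in ovarian cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CA-125 treatment-response dynamics in ovarian cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca125dyn)
```

## The problem

Serum CA-125 is the standard monitoring biomarker in high-grade serous
ovarian cancer (HGSOC). Patients typically receive several *lines* of
chemotherapy — groups of dosing cycles about 21 days apart — separated by
treatment-free intervals. CA-125 usually falls while a line is being given
and rises between lines, and the decline tends to weaken with each further
line as chemoresistance evolves. `ca125dyn` turns a patient's CA-125 time
series and dosing calendar into interpretable quantities at three levels:

1. **Data-based traits**: per-line regression slopes of log CA-125 —
   *resistance* (slope while on treatment, negative when the tumour responds)
   and *aggressiveness* (slope during the following treatment-free gap).
2. **Mechanistic model fits**: per-patient constrained least-squares
   estimates of compartmental growth/death rates.
3. **Survival stratification**: median-split Kaplan–Meier comparisons and
   multivariate Cox regression of the inferred quantities together with
   clinical covariates.

A synthetic cohort generator reproduces the statistical structure this
analysis assumes, so the entire pipeline is testable without access to any
patient-level data.

## Dynamical models

All models share the treatment indicator $\alpha(t)$, which is 1 while the
patient is inside the closed interval spanned by a line's first and last
cycle day (including intra-line gaps between cycles) and 0 otherwise.

### Sensitive/resistant two-compartment model (SR)

Treatment-sensitive cells $S$ and treatment-resistant cells $R$ follow

$$\frac{dR}{dt} = (1-\alpha)\gamma_R R - \alpha \delta_R R + \mu S, \qquad
  \frac{dS}{dt} = (1-\alpha)\gamma_S S - \alpha \delta_S S - \mu S,$$

with observed marker $C = R + S$. Growth rates $\gamma_S, \gamma_R$ act off
treatment; death rates $\delta_S, \delta_R$ act during lines. $\delta_R$ may
be negative — resistant cells that keep growing through therapy — while
$\gamma_R, \gamma_S, \delta_S, \mu, R(0)$ are constrained non-negative. The
transition $\mu S$ applies both on and off treatment. Three estimation
scenarios are exposed as variants: `SR_R0` (pre-existing resistant cells:
$\mu = 0$, $R(0) > 0$), `SR_mu` (resistance acquired by transition:
$R(0) = 0$, $\mu > 0$) and `single` (one compartment: $\mu = 0$,
$R(0) = 0$). An extended variant adds first-order marker turnover
$dC/dt = \delta_C (R + S - C)$ for the case where CA-125 tracks tumour
burden with a lag.

Within any interval of constant $\alpha$ the system is linear and
triangular, so `simulate_sr()` propagates it **exactly**: with per-capita
rates $a$ (resistant) and $b$ (sensitive, including the $-\mu$ drain),
$S(t) = S_0 e^{bt}$ and
$R(t) = R_0 e^{at} + \mu S_0 (e^{bt} - e^{at})/(b - a)$, replaced by the
analytic limit $R_0 e^{at} + \mu S_0 t e^{at}$ when $|b - a| < 10^{-12}$
(the limit is used rather than perturbing the rates, so the degenerate
equal-eigenvalue case is exact too). Propagation restarts at every regime
boundary and never integrates across an $\alpha$ switch. This closed form is
the production engine — it is fast enough for multistart fitting across a
cohort and has no step-size artefacts — while a general adaptive-step
integrator (`deSolve::lsoda`) is retained as an independent test oracle and
for the marker-turnover variant.

### Adaptive-dynamics model (AD)

Instead of two fixed types, a single population $N$ carries a continuous
chemoresistance level $x$ shared by all cells:

$$\frac{dN}{dt} = W(x)\,N, \qquad \frac{dx}{dt} = K \frac{\partial W}{\partial x},
  \qquad W(x) = (1-\alpha)\gamma(x) - \alpha\,\delta(x),$$

with logistic interpolations between the sensitive and resistant extremes,

$$\gamma(x) = \gamma_R + \frac{\gamma_S - \gamma_R}{1 + e^{B_\gamma x + A_\gamma}},
 \qquad \delta(x) = \delta_R + \frac{\delta_S - \delta_R}{1 + e^{B_\delta x + A_\delta}}.$$

Treatment pushes $x$ up (selecting resistance), treatment-free intervals
pull it down (selecting growth). The selection-response rate is fixed at
$K = 0.01$ per day. The gradient $\partial W/\partial x$ is evaluated
analytically and the logistic overflow-safely (branching on the exponent's
sign). Integration uses adaptive error control (relative tolerance
$10^{-8}$; $\log N$ is integrated so $N$ stays positive), restarting at each
$\alpha$ switch.

Two choices here were genuinely open. The initial resistance level $x_0$ is
not an estimated parameter and defaults to 0: the offsets $A_\gamma,
A_\delta$ absorb the choice of origin, and freeing $x_0$ would only add a
redundant direction. $B_\gamma, B_\delta$ are constrained non-negative so
the $x \to \pm\infty$ limits identify the resistant and sensitive extremes
as written. $N(0)$ is set to the first observed CA-125, mirroring the SR
initial condition.

## Data-based traits

`line_slope()` is ordinary least squares of natural-log CA-125 on time
(natural log throughout; slopes under other bases are a constant multiple).
`estimate_traits()` applies it per line: resistance over the measurements in
the line's closed on-treatment interval, aggressiveness over the
measurements strictly between that line's end and the next line's start
(after the final line, up to the last measurement). Boundary conventions
follow $\alpha$: a measurement on a line's last cycle day belongs to the
on-treatment window, and a measurement on the next line's first cycle day is
excluded from the gap. A slope is reported only where at least two
measurements fall in the window. Per-patient fixed-effect regression is used
throughout — these slopes also initialise the model fits — rather than a
population random-effects model, which is out of scope.

## Fitting

`ca125_fit()` minimises the sum of squared deviations between observed and
predicted **log** CA-125 over a fitting window, with $C(0)$ pinned to the
first observed value. Windows are `all` data or the first two/three/four
lines; a $k$-line window includes every measurement up to and including the
start day of line $k+1$ (the fitted lines plus the gaps that follow them)
and degenerates to all data when the patient has at most $k$ lines.

Constraints are enforced by smooth reparameterisation: non-negative rates
through a log map, $R(0)$ as a logit-mapped fraction of $C(0)$ (so
$S(0) \ge 0$ by construction — the upper bound $R(0) \le C(0)$ is implied by
$C = R + S$ with non-negative compartments), and $\delta_R$ and the AD
offsets unconstrained. Optimisation is multistart Nelder–Mead on the
unconstrained scale (20 restarts by default): the first start comes from the
data-based traits ($\delta_S, \gamma_S$ from first-line slopes; $\delta_R,
\gamma_R$ from later-line slopes when available, otherwise scaled copies),
two structured starts cover the primary-resistance and minor-resistant-clone
regimes, and the rest are Gaussian jitters of the first whose magnitude
cycles over several scales so both nearby and distant basins are probed.
The incumbent is then polished by alternating quasi-Newton (BFGS with
finite-difference gradients) and simplex restarts until no further
improvement: piecewise-exponential objectives are noticeably multimodal, and
the pure simplex often stalls on the curved valleys that remain near the
optimum, so the polish is what makes noiseless fits reproduce generating
parameters to high precision. Parameter sets whose simulated trajectory is
non-positive or non-finite receive a large finite penalty ($10^{12}$) so the
simplex can contract away from infeasible regions rather than aborting.
Fits are deterministic given (`seed`, control, data).

With $\mu = 0$ the two compartments of `SR_R0` are exchangeable, so the
objective has two symmetric global minima. Fits are reported in a canonical
labelling — the *resistant* compartment is the one with the smaller
on-treatment death rate — taken only when the swap keeps $\delta_S \ge 0$.
Comparisons with generating parameters must apply the same convention.

A window containing fewer measurements than free parameters plus one is
refused rather than fitted, preventing spurious exact fits.
`fit_cohort()` runs the patient × variant × window grid, recording failures
as non-converged rows instead of raising.

## Evaluation

* **Smoother ratio** (`rss_ratio`): RSS of a variable-span local-linear
  smoother divided by the model's RSS on the same log-scale points. The
  smoother (`supersmoother()`) follows the classic variable-span recipe:
  candidate spans 0.05/0.2/0.5 of the data compared pointwise by
  leave-one-out cross-validation, selected spans themselves smoothed at the
  mid span, final fit local-linear with the per-point span; below 10 points
  it falls back to the half-span fit, and below 5 it refuses. The bass and
  tension refinements of richer implementations are deliberately omitted;
  the base-R variable-span smoother is used in tests as an independent
  directional cross-check.
* **AIC** (`model_aic`): Gaussian likelihood with the variance profiled out,
  $\ln L = -\tfrac{n}{2}(\ln(2\pi\,\mathrm{rss}/n) + 1)$, and $k$ = free
  parameters + 1 for the variance, applied uniformly across variants so the
  convention cannot change a ranking.
* **Three R²** (`r_squared_triplet`): over the fitted window, over the
  points from the window's end through the end of the gap following the next
  line (short-term forecast), and over all later points. Each total sum of
  squares is centred on the evaluation subset's **own** mean — the
  convention under which a forecast worse than the subset mean is negative,
  which is exactly the out-of-sample failure mode of interest.

## Survival analysis

Overall survival is timed from the end of second-line treatment (patients
must survive through line 2 to be eligible, so timing from diagnosis would
build in survivorship bias). `build_survival_inputs()` resolves clinical
covariates from the records and merges model- or data-derived covariates
from a per-patient table, keeping complete cases only.
`median_split_km()` stratifies at the covariate median (ties go to the
lower group — deterministic and documented), with the log-rank test by
default and a Wilcoxon-type alternative. `cox_multivariate()` is a thin,
guarded wrapper around partial-likelihood estimation with Efron tie
handling from the `survival` package — this is routine statistics, not this
package's contribution; the bespoke content is the input construction and
split protocol. Covariate sets are always runtime arguments, never
hard-coded.

## The synthetic generator

`generate_cohort()` emulates the data structure the analysis assumes:

* **Schedules**: 2–6 lines; cycles 21 days apart; line spans and
  between-line gaps log-normal with medians 106 and 165 days (right-skewed
  positive durations parameterised by their median, since only medians and
  wide ranges are reported for real cohorts; log-sd 0.4).
* **Parameters**: truncated normal priors centred on across-patient
  summaries of the two-compartment model fits
  ($\delta_R$: $-0.00018 \pm 0.0127$; $\delta_S$: $0.04421 \pm 0.0241$;
  $\gamma_S$: $0.0142 \pm 0.0167$; $\gamma_R$: $0.01024 \pm 0.0127$, per
  day), and $\ln R(0)$ centred at $0.1208$ with prior sd widened to 1.0
  because the printed sd of that summary is inconsistent with its printed
  range and is treated as unreliable.
* **Patterns**: three qualitative response types with default weights
  0.6/0.25/0.15 — *fluctuating* (decline on each line, regrowth between;
  requires a clearly positive $\delta_S$), *primary resistant*
  ($\delta_R < 0$ and an initial resistant fraction of 30–80%, so CA-125
  rises through treatment after an initial dip) and *durable* (large
  $\delta_S$, slowed growth rates, CA-125 stays low). The weights are a
  design choice: the fluctuating pattern dominates real cohorts, primary
  resistance is a sizeable minority, durable responses the remainder.
* **Observation**: measurements at baseline (day 0, seven days before the
  first cycle, so $C(0)$ is always observed), every cycle day, two points
  per between-line gap and three follow-up points after the last line;
  multiplicative log-normal noise with sd 0.2 on log CA-125 (the noise
  model is an assumption — no measurement-error model is reported for
  CA-125 — and is configurable). Standard-normal draws are made
  unconditionally and scaled by the noise sd, so cohorts with different
  noise settings share every other random draw.
* **Survival**: exponential times from the end of line 2 with log-hazard
  $-7.1 + 25\gamma_S + 25\gamma_R - 25\delta_R$ (coefficients of magnitude
  25 give log-hazard contributions of roughly $\pm 0.3$ sd per parameter —
  strong enough for sign recovery at realistic cohort sizes), administrative
  censoring 2500 days after the anchor. Exponential rather than Weibull
  keeps the acceptance checks analytically tractable.
* An optional **drift** switches the true trajectory to
  treatment-insensitive exponential growth after a chosen line, emulating a
  resistant relapse that a model fitted on earlier lines cannot anticipate —
  this is what produces negative out-of-sample R².

What the generator does **not** emulate: correlated covariate structure of
real cohorts, drug-specific effects or partial cross-resistance, missing
visits and irregular sampling, marker turnover lag, or informative
censoring. Passing tests therefore demonstrate correctness of the machinery
and recoverability under the stated assumptions, not clinical performance
on real data.

## Numerical choices and limitations

* Equal-eigenvalue tolerance $10^{-12}$ on $|b - a|$; infeasibility penalty
  $10^{12}$; AD integration at relative tolerance $10^{-8}$
  ($10^{-6}$ inside fitting objectives, where speed matters more than the
  last digits).
* Test and acceptance problem sizes are chosen to exercise the claims at
  desk scale: 200 random systems for the oracle-equivalence check, 100
  noiseless patients (4-line schedules, ≥ 30 points) for parameter
  recovery, 200 noisy patients for error calibration, 100 patients for
  model discrimination, cohorts of 500 with 100 replicates of 150 for the
  survival checks.
* Parameters of patients whose resistant compartment never becomes visible
  within the observation span lie on a genuine likelihood ridge; recovery
  is then impossible in principle, which is why recovery is asserted as a
  high fraction rather than universally.
* No uncertainty quantification on fitted parameters (no profile
  likelihood or Bayesian machinery), no global optimiser, no hierarchical
  sharing across patients, no stochastic birth–death dynamics, no
  carrying-capacity growth, and no drug-concentration pharmacokinetics.
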