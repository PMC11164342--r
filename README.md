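# ca125dyn

Treatment-response dynamics of serum CA-125 in high-grade serous ovarian
cancer (HGSOC).

Patients with HGSOC receive chemotherapy in *lines* — groups of dosing
cycles, typically 21 days apart — separated by treatment-free gaps, and
CA-125 is the biomarker used to follow the response: it falls while a line
is delivered and rises between lines, and the decline weakens as
chemoresistance evolves. `ca125dyn` quantifies this at three levels:

* **Data-based traits.** Per line, the OLS slope of log CA-125 on time:
  *resistance* while on treatment (negative = response) and
  *aggressiveness* in the following gap.
* **Mechanistic models.** A two-compartment ODE of treatment-sensitive (S)
  and treatment-resistant (R) cells,

  ```
  dR/dt = (1 - α) γ_R R − α δ_R R + μ S
  dS/dt = (1 - α) γ_S S − α δ_S S − μ S,       C = R + S,
  ```

  with treatment indicator α ∈ {0, 1}, fitted per patient by constrained
  least squares on log CA-125 (variants: pre-existing resistance `SR_R0`
  with μ = 0, R(0) > 0; acquired resistance `SR_mu` with R(0) = 0, μ > 0;
  single compartment `single`) — propagated in closed form, exactly, across
  every treatment switch; and an adaptive-dynamics model `AD` in which a
  single population N carries a continuous resistance level x climbing the
  fitness gradient, dN/dt = W(x) N, dx/dt = K ∂W/∂x with
  W(x) = (1 − α) γ(x) − α δ(x) and logistic γ(x), δ(x) between the
  sensitive and resistant extremes.
* **Model comparison and survival.** RSS ratio against a variable-span
  smoother, AIC with profiled Gaussian variance, in-/out-of-sample R² over
  configurable fitting windows (first two/three/four lines or all data),
  median-split Kaplan–Meier and multivariate Cox regression of inferred
  traits with clinical covariates, timed from the end of second-line
  treatment.

A synthetic cohort generator (`generate_cohort()`) reproduces the
statistical structure of such cohorts — schedules with realistic line/gap
durations, three qualitative response patterns, multiplicative measurement
noise, survival linked to the generating parameters — so the full pipeline
is testable end to end without patient data. See the vignette
(`vignettes/ca125-dynamics.Rmd`) for the models, conventions and design
decisions.

## Worked example

```r
library(ca125dyn)

cfg    <- generator_config(n_patients = 30, seed = 42)
gen    <- generate_cohort(cfg)          # cohort + ground-truth table
cohort <- filter_eligible(gen$cohort)   # study inclusion criteria

estimate_traits(cohort[["P0012"]])
#> Data-based traits for patient P0012
#>  line_number  resistance aggressiveness n_on n_gap
#>            1 0.006766534    0.017836638    7     2
#>            2 0.009205459    0.011878543   10     3
#>            3 0.021836924    0.021802089    2     3
#>            4 0.028496339    0.013601241    3     3
#>            5 0.009280245    0.007686389    5     4
```

Positive on-treatment slopes on every line: this synthetic patient is
primarily resistant (CA-125 rises through therapy). Fitting the
two-compartment model with pre-existing resistance:

```r
fit <- ca125_fit(cohort[["P0012"]], "SR_R0",
                 control = fit_control(n_restarts = 10, seed = 1))
fit
#> CA-125 model fit (SR_R0, window all) for patient P0012
#>   RSS(log): 2.01215  n_obs: 43  converged: TRUE
#>   gamma_R   gamma_S   delta_R   delta_S   R0_frac
#>  0.010093  0.035886 -0.011118  0.028259  0.388000
```

The fit infers a resistant clone holding ~39% of the initial tumour burden
whose death rate under treatment is negative (δ_R = −0.011/day: net growth
through therapy), against a generating truth of γ_R = 0.0092,
γ_S = 0.016, δ_R = −0.0122, δ_S = 0.034, R(0)/C(0) = 0.376.
`coef()`, `predict()`, `residuals()`, `plot()` and `simulate()` methods are
available; `predict_future()` extrapolates a windowed fit over the full
schedule.

```r
evaluate_fit(fit)
#>   patient_id variant window    ratio      aic r2_fitted r2_next r2_later
#> 1      P0012   SR_R0    all 1.008276 2.362788  0.996622      NA       NA
```

A ratio near 1 means the mechanistic model tracks the data as closely as
the model-free smoother. Survival stratification on the inferred
resistant-cell growth rate:

```r
si <- build_survival_inputs(cohort, c("gamma_S", "gamma_R", "delta_R"),
        extra = gen$truth[c("patient_id", "gamma_S", "gamma_R", "delta_R")])
median_split_km(si, "gamma_R")
#> Median split on gamma_R at 0.01024
#>   groups (low/high): 15 / 15
#>   median survival: 587.93 / 135.88
#>  logrank chi-square = 8.104 , p = 0.00442
```

Patients with slow-growing resistant cells survive a median 452 days longer
in this small synthetic cohort, mirroring the direction built into the
generator's survival link (hazard increasing in γ_S and γ_R, decreasing in
δ_R).

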