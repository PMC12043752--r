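# dtcox — robust IPW Cox regression for doubly truncated survival data

Survival data are *doubly truncated* when a subject enters the sample
only if its event time `T` falls inside a random observation window
`[U, V]` — think of a retrospective registry that can only contain cases
diagnosed between the discovery of a disease and the end of the study,
with time measured from infection. Both early and late events are
missing, ordinary Cox regression is biased, and the usual
martingale-based standard errors do not apply.

`dtcox` is for biostatisticians analysing such registries (and for
anyone with interval-sampled event times, from epidemiology to
astronomy-style luminosity truncation). It provides, with **closed-form
standard errors everywhere — no bootstrap**:

* the NPMLE of the event-time CDF `F` and selection probabilities
  `a(t) = P(U ≤ t ≤ V)/α` via the EM algorithm, with the
  strong-connectedness identifiability check;
* exact closed-form plug-in influence-function matrices for the NPMLE —
  the engine behind every variance in the package;
* inverse probability weighted Cox regression solving

  ```
  Σ_i  w(T_i)/â(T_i) · [ x_i − x̄_â(T_i, β) ]  =  0
  ```

  where every subject at risk is weighted by `1/â(T_j)` in the risk-set
  average `x̄_â`, and the time-varying weight `w(t)` is chosen from
  unit, stabilized `â(t)`, **survival `1 − F̂(t)`** (the robust default:
  events are weighted by the estimated fraction of the pre-truncation
  population still at risk, taming influential late events),
  Fleming–Harrington `F̂^r (1−F̂)^s`, and stabilized products;
* three nested sandwich variances (naive / adjusted for the estimated
  weights / robust to model misspecification), an IPW Breslow baseline
  hazard with influence-based confidence bands;
* sensitivity analysis for positivity violations: when events are only
  observable on a window `[L, R]` inside the support, the at-risk
  process is inflated by `p^exp(x'β)/(1 − p^exp(x'β))` for an assumed
  truncated baseline mass `p = S0(R)/S0(L)`, refit over a grid of `p`,
  with union-of-CI *sensitivity intervals*;
* nonparametric diagnostics: a stratified selection-probability
  comparison (`sup |π̂(t|s) − π̂(t)|` with a simulated Gaussian null and
  uniform band), conditional Kendall's tau with a
  constrained-permutation p-value, and tests for ignorable sampling
  bias (`a(t) ≡ 1`);
* a seeded synthetic-data engine reproducing the validation designs
  (wide-window, contaminated, and positivity-violating variants).

## Worked example

```r
library(dtcox)

design <- dt_sim_design(n = 300)         # doubly truncated Cox data
s      <- dt_generate(design, seed = 42) # ~36% of subjects truncated away

fit <- dtcox(dtrunc(T, U, V) ~ x1 + x2, data = s, weight = "survival")
summary(fit)
#> Robust IPW Cox regression for doubly truncated data
#>   n = 300, weight: w(t) = 1 - F(t), robust standard errors
#>
#>          coef  exp(coef)         se          z          p  lower upper
#> x1 9.3892e-01 2.5572e+00 1.5231e-01 6.1646e+00 7.0646e-10 0.6404 1.237
#> x2 5.5606e-01 1.7438e+00 2.7896e-01 1.9934e+00 4.6222e-02 0.0093 1.103
#>
#> Standard errors by variance estimate:
#>      naive     adj  robust
#> x1 0.14471 0.15143 0.15231
#> x2 0.27277 0.27729 0.27896
```

The data were generated with true log hazard ratios `(1, 1)`; both
estimates cover the truth. The `naive` column ignores that the inverse
weights were estimated and is slightly anti-conservative; `adj` and
`robust` add the closed-form influence corrections. A positivity
sensitivity analysis and the quasi-independence diagnostic:

```r
sens <- dtcox_sensitivity(fit, p_grid = seq(0, 0.2, by = 0.1))
sensitivity_interval(sens, 0.2)   # union of 95% CIs for p ≤ 0.2
#>          lower    upper
#> x1 0.640403340 1.388310
#> x2 0.009316254 1.255352

qi <- dt_quasi_independence_test(s, strata = s$x1, n_null = 2000, seed = 9)
qi$p_value
#> [1] 0.225    # no evidence against quasi-independent truncation
```

The sensitivity interval for `x1` says: even if up to 20% of the
baseline mass were unobservable due to a positivity violation, the
plausible range for the log hazard ratio stays within `[0.64, 1.39]`.

Other entry points: `dt_npmle()`, `dt_influence()`, `dt_baseline()`,
`dt_ignorable_bias_test()`, `conditional_kendall_tau()`,
`dt_run_coefficient_experiment()` /
`dt_run_sensitivity_experiment()` (simulation studies), and a thin
command-line wrapper `inst/cli/dtcox.R` with subcommands
`generate | npmle | fit | sensitivity | diagnose | simulate`.

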