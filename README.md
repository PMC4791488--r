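# ppestim

Power and sample-size analysis for hypothesis tests in (non-linear)
mixed-effects models, for people who plan trials by simulation:
pharmacometricians, biostatisticians and anyone else whose analysis model has
no closed-form power formula.

## The idea

A likelihood-ratio (or Wald) test with *k* degrees of freedom is
asymptotically central chi-square under H0 and **non-central** chi-square
with non-centrality parameter λ under the alternative.  The classical Monte
Carlo power estimate (MCPE) simulates S datasets, refits each with the full
and reduced model, and counts rejections

> π̂_M = #{ t_s > χ²₁₋α,k } / S,

throwing away everything about each statistic except one bit.  Parametric
power estimation (PPE) instead estimates λ by maximum likelihood from the
same statistics,

> λ̂ = argmax_λ Σ_s log f_χ²(t_s; k, λ),

and computes power analytically,

> π̂_P = 1 − F_χ²(χ²₁₋α,k; k, λ̂).

Because λ is proportional to the number of subjects when the per-subject
design is replicated (λ_N = λ_ref · N / N_ref), a single batch of
simulations at one study size yields the **entire power-versus-study-size
curve** — and the estimator is roughly twice as simulation-efficient as
counting rejections.

The package provides

* `ppe()` — the λ fitter, a classed model object with `print`, `summary`,
  `coef`, `logLik`, `predict` (power curves), `plot`, `simulate`, `confint`
  methods;
* `ppe_bootstrap()` / `ppe_diagnostic()` — parametric-bootstrap confidence
  intervals for the Monte Carlo uncertainty, and an empirical-CDF band check
  of the non-central chi-square assumption;
* `mcpe()` / `mcpe_power_curve()` — the reference Monte Carlo estimator;
* `sse_engine()` + `simulate_dataset()` / `fit_model()` — a compact
  simulate-and-estimate engine for binary (repeated Bernoulli, adaptive
  Gauss–Hermite), Weibull time-to-event (exact likelihood, with a batched
  Newton fitter for 10⁴-replicate studies), Poisson count (Laplace) and
  Gaussian-linear disease-progression models (exact marginal likelihood);
* `run_method_comparison()` / `run_coverage_study()` — the evaluation
  harness (relative bias, SD, range, bootstrap coverage);
* `read_statistics()` — import of statistics from any external estimation
  software (a `statistic` column, or `ofv_full`/`ofv_reduced` pairs on the
  −2·log-likelihood convention), so ODE-based models estimated elsewhere can
  be analysed too;
* `exec/ppe` — a thin command-line wrapper (`fit`, `sse`, `evaluate`,
  `diagnose`).

## Worked example

Estimate the power curve of the built-in Weibull time-to-event trial
(N = 200, covariate effect 0.4 on the log scale parameter, censoring at
T = 10) from 400 simulate–refit replicates:

```r
library(ppestim)
eng   <- sse_engine("tte")
stats <- sse_statistics(eng, n = 200, s = 400, seed = 7)
fit   <- ppe(stats, df = 1, n_ref = 200)
fit
#> Parametric power estimation (PPE) fit
#>   statistics: 400  df: 1  alpha: 0.05
#>   lambda: 28.48
#>   power at reference size N = 200 : 0.9996

predict(fit, n = c(50, 100, 150, 200))
#>     n   lambda     power
#> 1  50  7.12009 0.7606490
#> 2 100 14.24018 0.9651344
#> 3 150 21.36027 0.9961133
#> 4 200 28.48036 0.9996332
```

Reading: the fitted non-centrality at the simulated size is λ̂ ≈ 28.5 —
this design is heavily over-powered at N = 200 (π ≈ 0.9996) — and the linear
λ-scaling shows a 50-subject trial would still reach ≈ 76% power.  Each
curve point is power at that study size; add `interval = "bootstrap"` for
95% Monte Carlo confidence bands.

The distributional assumption behind those numbers is checked by the
bootstrap CDF band:

```r
ppe_diagnostic(fit, B = 500, seed = 8)
#> PPE distributional diagnostic (envelope band, 474 retained bootstrap draws)
#>   fraction of statistics outside the band: 0.000
```

A fraction near 0 means the statistics are compatible with a non-central
chi-square; boundary-constrained hypotheses (mass of statistics at 0) push
it far above the 0.05 warning threshold.

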