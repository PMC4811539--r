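# burstfit

Human activity is bursty: the waiting time τ between one person's
consecutive messages spans five orders of magnitude, with a plateau of
quick responses at short times, a power-law body, and an exponential
cutoff at long times.  No single classical family (exponential, Pareto
above a cutoff x_m, Weibull, log-normal) tracks all three regimes, which
is why power-law fits of such data only work after cropping a large share
of the short waits.

`burstfit` is for researchers who analyse per-individual event logs
(messaging, email, correspondence, or any renewal-like action stream) and
want a single interpretable model across all timescales.  It models the
*hazard* of acting after a wait τ,

    λ(τ | θ) = λ₀ / ((τ/t₀)^α + 1) + λ∞,     θ = {λ₀, t₀, α, λ∞},

and derives the waiting-time law through the survival-analysis identities
S(τ) = exp(−∫₀^τ λ) and P(τ) = λ(τ) S(τ).  λ₀ sets the quick-response
rate, t₀ the timescale where burstiness emerges, α the heterogeneity of
the power-law regime, and λ∞ the long-time rate that produces the
exponential tail and dominates the mean interevent time.  Constant λ
recovers the Poisson process; λ = γ/τ (above a cutoff) gives a Pareto
density with exponent 1+γ; λ = γ/τ^a with a < 1 is exactly Weibull.

The package provides:

* exact distribution functions (`hmsp`, `chmsp`, `smsp`, `dmsp`, `pmsp`,
  `qmsp`, `rmsp`, `msp_mean`) with machine-precision quadrature of the
  cumulative hazard;
* per-individual maximum-likelihood fitting (`msp_fit`, multi-start
  quasi-Newton in log-parameter space) with the usual methods
  (`coef`, `logLik`, `summary`, `predict`, `simulate`, `residuals`,
  `plot`);
* the baseline families (`fit_baseline`, `pareto_tune_xm`, `dpowhaz`,
  `dpareto` and friends);
* goodness-of-fit tests against any fitted model (`gof_ks`, `gof_chisq`,
  `gof_cvm`; classical p-values by default, parametric bootstrap on
  request) and the population protocol (`evaluate_population`: average
  statistic and pass rate per family; `crop_curve`: average KS p-value
  versus cropped data fraction);
* an exact cohort simulator with population heterogeneity
  (`population_config`, `sample_population`, `to_event_log`) and
  event-log ingestion (`read_event_log`, `intervals_from_timestamps`,
  `cohort_fit_table`, `summarize_population`);
* a thin command-line interface (`inst/cli/burstfit.R`) with
  `fit`, `simulate`, `gof` and `crop` subcommands over two-column
  (id, seconds) delimited logs.

## Worked example

```r
library(burstfit)
theta <- msp_params(lambda0 = 0.02, t0 = 30, alpha = 1.45, lambda_inf = 1e-4)
set.seed(1)
tau <- rmsp(5000, theta)        # exact draws by cumulative-hazard inversion
fit <- msp_fit(tau, seed = 1)
summary(fit)
#> Multiscale interevent-time model fit
#>   n = 5000 observations, log-likelihood = -35445.832 (5 starts, best = #3)
#> Multiscale hazard parameters:
#>   lambda0    = 0.02012  (events/s, short-time rate)
#>   t0         = 29.81  (s, critical timescale)
#>   alpha      = 1.441  (burst-regime exponent)
#>   lambda_inf = 9.317e-05  (events/s, tail rate)
#>   implied mean interevent time: 2578.3 s
#>   KS goodness of fit: D = 0.0078, p = 0.9246
```

The fit recovers the generating parameters (0.02, 30 s, 1.45, 1e-4)
closely; the KS p-value of 0.92 says the fitted law is statistically
indistinguishable from the 5000 observed waits.  `plot(fit)` overlays the
fitted density and survival on the log-binned data; `residuals(fit)`
returns Cox–Snell residuals (standard-exponential under a correct model).

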