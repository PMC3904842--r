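# pulsedecon

Sparse blind deconvolution of pulsatile hormone time series.

Serum cortisol (and other pulsatile hormones) is produced in discrete
secretory bursts — roughly 15 to 22 per day — that pass through simple
first-order kinetics before being sampled, typically every 10 minutes.
`pulsedecon` recovers, from a single sampled 24-hour series, **both**

* the secretory events: how many, at which minute, with what amount, and
* the kinetic rate constants: the infusion rate θ₁ (secretory compartment →
  blood) and the clearance rate θ₂ (elimination from blood),

by coordinate descent that alternates sparse nonnegative input recovery
(FOCUSS+ with generalized-cross-validation–selected regularization) and
constrained kinetic least squares on the cone θ₁ ≥ 4θ₂ > 0. The input lives
on a 1-minute grid (1440 candidate minutes against 144 observations), so the
system is massively underdetermined and sparsity is what makes it
identifiable.

See the methods vignette (`vignettes/methods.Rmd`) for the model, the
algorithm, and every numerical convention.

## Worked example

Simulate a 24-hour dataset with known ground truth, deconvolve it, and score
the recovery. `simulation_suite()` builds one dataset per reference
participant — ten published kinetic-parameter/noise-level pairs from 24-h
serum cortisol profiles — with statistically matched synthetic pulse trains.

```r
library(pulsedecon)

suite <- simulation_suite(seed = 1)
ds <- suite[[9]]                    # participant 9: theta = (0.0361, 0.0090), sigma = 0.35
fit <- deconvolve(ds$series, n_starts = 3, seed = 9)
fit
#> <decon_fit> sparse deconvolution of a sampled hormone series
#>   observations : 144 samples every 10 min (+ y0 = 5)
#>   theta1 (infusion)  : 0.0365 /min
#>   theta2 (clearance) : 0.0091 /min
#>   pulses : 18   R-squared : 0.9958
#>   lambda : 0.3392   cost : 25.46   starts : 3   seed : 9
```

The fit is an ordinary broom-style object:

```r
tidy(fit)                           # one row per recovered secretory event
#> # A tibble: 18 × 2
#>   time_min amplitude
#>      <int>     <dbl>
#> 1      100      3.94
#> 2      280      9.53
#> 3      330      4.62
#> # ...

glance(fit)
#>       theta1     theta2 n_pulses r_squared final_lambda final_cost
#> 1 0.03647252 0.00911813       18 0.9957553    0.3391639   25.45592

augment(fit)                        # observations + .fitted + .resid
autoplot(fit)                       # needles, samples, fitted curve
plot_residual_diagnostics(fit)      # autocorrelation + QQ panels
```

Against the known truth:

```r
evaluate_recovery(ds$theta, ds$pulses, fit, window = 30)
#>   theta1_pct_error theta2_pct_error pulse_count_error max_timing_error
#> 1         1.031911         1.312556                 2               15
#>   n_undetected n_extra r_squared window
#> 1            1       3 0.9957553     30
```

Real data enter through `read_series()` (CSV with columns
`time_min,concentration`, first row at time 0; interior gaps are linearly
interpolated), and results round-trip losslessly through
`write_result()`/`read_result()` JSON.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/pulsedecon.R simulate   --seed 11 --out-dir sims/
Rscript inst/cli/pulsedecon.R deconvolve --input series.csv --seed 7 \
    --n-starts 10 --out result.json --pulses-out pulses.csv
Rscript inst/cli/pulsedecon.R evaluate   --truth truth.json \
    --result result.json --out metrics.json
```

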