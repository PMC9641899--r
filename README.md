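# serialbias

Trial-to-trial history effects in circular estimation tasks (such as
motion-direction report) mix two opposite biases: a **repulsive
aftereffect** pushing the current estimate away from the previous stimulus,
and an **attractive serial dependence** pulling it toward the previous
response. Because stimulus and response are almost perfectly correlated
across trials, the two can only be separated jointly. `serialbias` is an R
package for psychophysicists who want to do that separation end to end:

* **Synthetic task and response generation** — balanced random-walk
  stimulus sequences (±20°/±40°/±80°/±180° groups; block lengths
  101/100/103/109) and responses from a generative bias-curve model.
* **Idiosyncratic-bias correction** — per-subject sinusoidal, polynomial,
  or Gaussian-process regression of error on stimulus direction, with a
  within-block shuffle control, plus the outlier-exclusion cascade.
* **Descriptive models** — first-derivative-of-Gaussian (DoG) bias curves
  `y = x a w c exp(-(wx)^2)` (peak height `a` at `x = l = 1/(sqrt(2) w)`),
  combined into Stimulus, Response, Stimulus & Response, and
  Attraction & Repulsion models with free bias centres
  `beta * Response[t-1] + (1 - beta) * Stimulus[t-1]`, fitted by a
  hierarchical Bayesian Metropolis–Hastings sampler (compiled core, 4
  chains, Gelman–Rubin diagnostics) with von Mises trial noise
  `y ~ vonMises(mu, 1/sigma^2)`.
* **Model comparison** — per-subject AIC at posterior-mean estimates with
  BCa bootstrap intervals on mean differences.
* **Bias analytics** — marginal sliding-window curves, the joint 2-D bias
  map over (previous-stimulus, previous-response) offsets, conditional
  curves, and ggplot2 `autoplot()` methods.
* **Ideal-observer simulation** — Poisson population encoding with von
  Mises tuning, rapid gain adaptation (stimulus- or spike-count-driven),
  and recursive Bayesian decoding through a von-Mises-plus-uniform
  propagation kernel.

## Worked example

Simulate a small cohort from the generative model (repulsion −5° wide 38°,
attraction +8° narrow 29°, 8° response noise), fit the Stimulus & Response
model, and inspect the population posterior:

```r
library(serialbias)
library(dplyr)

trials <- simulate_cohort(n_subjects = 8, n_blocks = 15, seed = 42) |>
  group_by(subject, block) |>
  mutate(excluded = trial == min(trial)) |>
  ungroup()

fit <- fit_bias_model(trials, bias_model("stim_resp"),
                      control = mcmc_control(scale = "test"), seed = 7)
summarize_posterior(fit)
#> # A tibble: 10 x 5
#>    parameter    mode    mean    lower  upper
#>    <chr>       <dbl>   <dbl>    <dbl>  <dbl>
#>  1 mu_a_stim -5.32   -5.21   -5.95    -4.52
#>  2 mu_l_stim 41.2    41.3    37.4     45.9
#>  3 mu_a_resp  8.15    8.15    7.51     8.77
#>  4 mu_l_resp 29.1    29.6    27.9     31.5
#>  5 mu_sigma   7.96    7.97    7.84     8.09
#>  ...

max(gelman_rubin(fit)$rhat)
#> [1] 1.012295
```

The population means recover the generating values (−5, 38, +8, 29, 8
degrees) within their 95% credible intervals, and all chains converge
(`Rhat < 1.1`). The joint bias map of the same data shows the signature
structure — errors decrease along the previous-stimulus axis and increase
along the previous-response axis:

```r
map <- joint_bias_map(trials, min_subjects = 2)
joint_map_gradients(map)
#> # A tibble: 1 x 2
#>   slope_prev_stim slope_prev_resp
#> 1          -0.080           0.22     # repulsion x attraction
autoplot(map)
```

The ideal observer reproduces the same structure from spikes:

```r
obs <- simulate_observer(simulate_stimuli(task_design(40), 5, seed = 1),
                         observer_config(), seed = 2)
```

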