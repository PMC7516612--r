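# nestshift

Bayesian evidence and posterior estimation for binned spectra by **nested
sampling**, with a constrained random-walk live-point search and
**mean-shift cluster recognition** for multimodal likelihoods.

## The problem it solves

Comparing spectral models — how many peaks? is there a modulation on top of
the decay? — is a marginal-likelihood question. For a model `M` with
parameters `a` and uniform box priors, the evidence

```
E(M) = ∫ L_M(a) π(a) d^J a
```

is what turns into posterior model odds (`ln E` differences of ~0.9 are
about two sigma). Nested sampling computes it by tracking the prior volume
`X` enclosed by rising likelihood contours: `K` *live points* are drawn
from the prior, and at each step the worst one (likelihood `L_m`) is
recorded with volume weight from the deterministic shrinkage
`X_m ≈ exp(-m/K)` (trapezoid rule) and replaced by a new point with
`L > L_m`. The recorded chain yields `ln E`, the information gain `H`, the
Bayesian complexity, and weighted posterior summaries for every parameter.

The hard part is finding replacement points when the likelihood has many
maxima — for example the `P! = 24` permutation-degenerate maxima of four
identical-width peaks. Here the replacement search is a *lawn-mower* random
walk (steps `f·r·σ` under the hard constraint `L ≥ L_m`), with two fallback
strategies (barycenter segment draw, per-coordinate mixing of live points)
and an escalation rule: after `Nt × NNt` consecutive failures the live
ensemble is clustered by **mean shift** (truncated flat or Gaussian kernel
on min-max-normalized points; the number of clusters is an output, not an
input), and subsequent walks use the standard deviation of the start
point's *cluster* instead of the global one. That single change lets the
sampler populate and hold all degenerate modes at once, which shows up as
a much smaller run-to-run scatter of `ln E`.

Intended users: anyone fitting low-count Poisson or Gaussian spectra who
needs evidences for model selection, and anyone studying the sampler
itself — every algorithmic piece (walk, fallbacks, clustering, shrinkage
bookkeeping) is exported and unit-tested separately.

## Worked example

Simulate a two-peak spectrum, fit it, and compare against a one-peak model:

```r
library(nestshift)

spec <- four_peaks_spec(n_channels = 60, positions = c(18, 42),
                        areas = c(250, 400), width = 2.5, bg = 1)
d <- gen_peak_spectrum(spec, seed = 71)

space2 <- param_space(c("bg", "w", "x0_1", "x0_2", "A_1", "A_2"),
                      lower = c(0, 0.5, 1, 30, 0, 0),
                      upper = c(5, 8, 30, 60, 600, 600))
fit2 <- ns_fit(ns_model("gauss_peaks", npeaks = 2), d, space2,
               ns_config(K = 300, runs = 3, N = 10, f = 0.3), seed = 71)
print(fit2)
#> Nested-sampling fit of model 'gauss_peaks' (J = 6)
#>   lnE = -134.1581 +/- 0.1876  (3 runs)
#>   information gain H = 14.722 nats, complexity C_b = 4.96
#>   25847 total steps, 0 cluster analyses

fit1 <- ns_fit(ns_model("gauss_peaks", npeaks = 1), d,
               param_space(c("bg", "w", "x0_1", "A_1"),
                           c(0, 0.625, 1, 0), c(5, 6.25, 60, 845)),
               ns_config(K = 300, runs = 3, N = 10, f = 0.3), seed = 73)
log_bayes_factor(fit2$lnE, fit1$lnE)
#> [1] 300.558
```

`lnE = -134.16 ± 0.19` is the two-peak evidence with its repeat-run
uncertainty; `H ≈ 15` nats says the data compress the prior by `e^15`;
the log Bayes factor of ~300 in favor of two peaks is overwhelming (0.9
would already be "two sigma"). `summary(fit2)` prints the per-parameter
posterior table (mean, median, sd, 68/95/99% intervals); `coef`, `vcov`,
`predict`, `residuals`, `simulate` and `plot` behave as for any fitted
model object.

The multimodal flagship — four identical-width peaks whose 24 permutation
modes the cluster recognition resolves — runs with the reference settings:

```r
spec <- four_peaks_spec()                      # 24 exchangeable modes
d    <- gen_peak_spectrum(spec, seed = 99)
fit  <- ns_run(benchmark_model(spec), d, benchmark_space(spec),
               ns_config(K = 2000, N = 20, f = 0.2, Nt = 200, NNt = 2,
                         kernel = "gaussian", D = 0.6, ell = 0.2), seed = 1)
fit$cluster_history                            # clusters found per analysis
```

A thin command-line front end lives at `inst/cli/nestshift`
(`run`, `simulate`, `cluster`, `summarize` sub-commands) for shell use.

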