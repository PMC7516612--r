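---
title: "Nested sampling with mean-shift cluster recognition: models, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested sampling with mean-shift cluster recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestshift)
```

# The problem

Bayesian model comparison for binned spectra hinges on the evidence
(marginal likelihood)

$$ E(M) = \int L_M(a)\,\pi(a)\,\mathrm{d}^J a, $$

the integral of the likelihood over the $J$-dimensional parameter space
weighted by the prior. Posterior odds between two models are
$E_1/E_2$ times the prior odds; as a rule of thumb a difference of 0.9 in
$\ln E$ corresponds to roughly a two-sigma preference. The integral is the
hard part: for low-count spectra with several exchangeable components (for
example $P$ identical-width peaks, whose likelihood has $P!$
permutation-degenerate maxima) it is both high-dimensional and strongly
multimodal.

`nestshift` computes $E$ by nested sampling with a constrained random-walk
live-point search, escalation fallbacks, and mean-shift cluster recognition
of the live-point ensemble for multimodal problems. The main entry point is
`ns_fit()`, which returns a classed object with the usual modelling methods
(`print`, `summary`, `coef`, `vcov`, `predict`, `residuals`, `simulate`,
`plot`, `logLik`).

# Nested sampling

Nested sampling rewrites the evidence as a one-dimensional integral
$E = \int_0^1 L(X)\,\mathrm{d}X$ over the prior volume
$X(L^*) = \int_{L(a) > L^*}\pi(a)\,\mathrm{d}^Ja$ enclosed by likelihood
iso-contours. A set of $K$ *live points* is drawn from the prior; at each
step $m$ the worst live point (lowest $L_m$) is recorded and replaced by a
new point with $L > L_m$. Order statistics give the expected shrinkage
$X_m \approx e^{-m/K}$ per discard; the package uses this deterministic
expectation throughout (`shrinkage_lnX()`), which the test suite validates
against a literal Monte-Carlo simulation of the order-statistic process.

## Volume weights, termination, and the live-point remainder

The evidence sum uses trapezoid volume slices
$\Delta X_m = (X_{m-1} - X_{m+1})/2$ (`trapezoid_weight()`). Two end caps make
the slices an *exact* partition of the prior mass:

* the first slice is $\Delta X_1 = 1 - (X_1+X_2)/2$ (the plain trapezoid
  value $(1 - X_2)/2$ under-counts the initial boundary by $O(1/2K)$ and the
  slices would not sum to 1);
* after termination at step $M$, the remaining volume
  $(X_M + X_{M+1})/2$ is split evenly over the $K$ surviving live points,
  each contributing at its own likelihood.

With this convention $\sum_m \Delta X_m + X_{\mathrm{rem}} = 1$ to machine
precision, and a constant likelihood $L \equiv c$ yields $\ln E = \ln c$
exactly for any $K$ and seed — both are asserted in the tests. All evidence
arithmetic is done in log space with `logsumexp`-style accumulation.

A run terminates when the largest possible remaining contribution
$\max(L_{\mathrm{live}})\,X_m$ drops below `stop_tol` (default $10^{-5}$)
times the accumulated evidence, or at `max_steps`.

## Outputs

Each run reports $\ln E$, the information gain
$H = \sum_m (w_m/E)\ln L_m - \ln E$ (the prior-to-posterior
Kullback–Leibler divergence, in nats; $\sqrt{H/K}$ is the theoretical
evidence uncertainty), the Bayesian complexity
$C_b = -2(\langle \ln L\rangle_{\mathrm{post}} - \ln L_{\max})$, and
weighted posterior summaries (mean, median, sd, central 68/95/99%
intervals from the weighted empirical quantile function). $C_b$ is anchored
at the best sampled point rather than the likelihood at the posterior mean:
for permutation-degenerate posteriors the posterior mean lies between modes
and its likelihood is meaningless.

`ns_fit()` repeats the run `runs` times (default 16) from independent
starting live sets; $\delta(\ln E)$ is the sample standard deviation
(n−1) of the per-run $\ln E$ — the natural, assumption-free uncertainty
estimate. With a single run it is reported as `NA` with a warning.
Posterior samples are pooled across runs with per-run normalized weights.

# Likelihoods and model families

Counting spectra `(channel, counts)` use the Poisson log-likelihood
$\ln L = \sum_i [n_i \ln\lambda_i - \lambda_i - \ln n_i!]$ with
$0\ln 0 := 0$; a zero rate under observed counts gives $-\infty$, which the
sampler simply rejects. The $\ln n_i!$ term is kept so that $\ln E$ values
are absolute and comparable across models. Measured spectra
`(channel, y, sigma)` use the Gaussian log-likelihood including its
normalization.

Two built-in families cover the benchmark problems:

* `gauss_peaks`: $P$ Gaussian peaks of shared width $w$ on a flat
  background, parameterized by *areas* rather than heights
  ($f(x) = bg + \sum_p A_p/(w\sqrt{2\pi})\,e^{-(x-x_{0p})^2/2w^2}$). The
  area parameterization makes the peak integral exactly $\sum_p A_p$
  (tested against quadrature) and decouples amplitude from width.
* `mod_decay`: exponential decay with sinusoidal modulation,
  $f(t) = C\,e^{-t/\tau}\,[1 + a_{\mathrm{mod}}\cos(\omega t + \varphi)] + bg$.
  The literature source for this measurement parameterizes the decay rate
  differently; since no reference data are redistributed here, the
  benchmark only requires this declared generative form.

Custom models plug in either as a prediction function `function(x, a)`
(combined with the dataset's counting statistic) or as a direct
log-likelihood `function(a)` — the latter is how the analytic toy problems
in the test suite are expressed.

# The live-point search

## Lawn-mower walk

A replacement point is sought by a random walk from a randomly chosen live
point: proposals $a \to a + f\,r\,\sigma$ (componentwise; $r_j$ standard
normal by default, uniform on $[-1,1]$ optionally), accepted iff inside the
prior box and $\ln L \ge \ln L_m$. The walk runs until $N$ accepted jumps.
The scale $\sigma$ is the per-dimension standard deviation of the current
live points — or, when cluster labels exist, of the walk start's cluster
only, which is what makes multimodal exploration efficient. The efficiency
criterion $f \times N \gtrsim 1$ (walks should cover about one standard
deviation) is checked by `validate_ns_config()`, which warns rather than
errors; the recommended operating range is $N = 20$–$40$, $f = 0.1$–$0.2$.

Two deliberate conventions:

* **Ties are accepted** ($\ge$ rather than $>$). On a likelihood plateau a
  strict inequality can never be satisfied and the flat-likelihood identity
  $\ln E = \ln c$ would be unreachable; for continuous likelihoods ties
  have measure zero, so nothing else changes.
* **Out-of-bounds proposals count as failures** and are re-drawn, never
  clipped or reflected — clipping would bias the hard-constraint walk
  toward the boundary.

## Walk-length accounting and a known systematic

Counting *accepted jumps* (the default, `walk_unit = "acceptances"`) is the
historical rule for this sampler, but it has a quantifiable side effect:
the chain observed only at acceptance times is the *jump chain* of the
Metropolis kernel, whose stationary density is proportional to the local
acceptance probability. Near the hard likelihood contour the acceptance
probability is depressed, so the boundary layer of each constrained region
is slightly under-sampled, the recorded thresholds rise a little too fast,
and the evidence acquires a small upward offset that grows with the step
size $f\sigma$ and does not vanish with $K$. Setting
`walk_unit = "proposals"` counts every proposal (a rejection holds the
chain in place), which is plain Metropolis with a uniform stationary law on
the constrained region and removes the offset at the price of a shorter
effective walk per unit cost. The test suite demonstrates the sign of the
offset on a narrow unimodal toy, and the analytic-recovery acceptance
tests (which assert agreement with closed-form evidences within
$3\sqrt{H/K}$) therefore run the `"proposals"` variant; all structural
benchmarks (cluster counts, trigger economy, scaling) keep the faithful
default.

## Escalation, fallbacks and the cluster trigger

`nt` counts *consecutive* failed proposals: any accepted proposal (or
successful fallback) resets it. At every `Nt`-th consecutive failure the
walk escalates and one of two fallback strategies is chosen with a fair
coin:

* **barycenter fallback** — a candidate drawn uniformly on the segment
  between the live-point barycenter and the last failing chain point
  (favors re-centering);
* **coordinate mix** — a synthetic candidate whose $j$-th component comes
  from an independently chosen random live point (preserves the empirical
  marginals; good at jumping between peripheral maxima).

A successful fallback candidate becomes the new walk start and the walk
continues with its remaining budget; a failed candidate restarts the walk
from a fresh random live point with the failure counter preserved. Once
`Nt * NNt` consecutive failures accumulate, the mean-shift cluster analysis
is run on the live ensemble, every point is labelled, and the search
restarts from a random live point using its cluster's scale. New live
points inherit the cluster label of their walk start until the next
analysis.

The *consecutive* reading of the counter is a deliberate design decision.
A cumulative counter (total failures since the last analysis) sits exactly
at the marginal operating point: a walk limping at a few percent acceptance
still makes progress, yet accumulates hundreds of failures and would fire
cluster analyses every few steps — we measured hundreds of analyses per
run on the four-peak benchmark under that reading, with each analysis
costing $O(K^2)$. Under the consecutive rule a walk at 5% acceptance
reaches 200 consecutive failures with probability $0.95^{200} \approx
3\times10^{-5}$, so only genuinely stuck searches (a starved mode whose
basin has fallen below the threshold, the initial multimodal lock-in)
escalate, and full runs of the four-peak benchmark invoke the analysis a
handful of times — the intended economy of the method. A hard cap
(`max_cluster_analyses`, default 50) turns a pathological run into an
error rather than an endless loop.

Singleton clusters would have a floored, essentially zero scale; a walk
started there would "accept" its own position forever and flood the live
set with duplicates. Clusters with fewer than two members therefore fall
back to the global scale; the floor
(`sigma_floor_rel * (upper - lower)`) still applies to every reported
cluster scale.

# Mean-shift cluster recognition

Before clustering, live points are min-max normalized per dimension to
$[0,1]$ so the distances `D` and `ell` are dimensionless; a degenerate
dimension (max = min) maps to 0.5, is flagged, and is excluded from
distance computations. Every point seeds a query that is iterated to the
kernel-weighted mean of its neighbors within Euclidean radius `D`:
flat kernel (weight 1) or Gaussian kernel $e^{-d/\ell}$ (distance, not
squared distance; both kernels are truncated at `D`). Iteration stops when
the largest displacement falls below `ms_tol` ($10^{-4}$ normalized units)
or after `ms_max_iter` (100) iterations. Converged queries within
`merge_dist` (0.05) of one another are merged by single linkage into one
cluster; isolated points form singletons. The cluster count is an output,
never an input — the property that motivates mean shift over k-means-type
methods for an unknown number of likelihood modes.

By default the *data stay fixed* and only the queries move (the textbook
mode-seeking iteration). The alternative *blurring* iteration — the
shifted ensemble replaces the data each round — is available
(`ms_blurring`, `mean_shift(blurring = TRUE)`) but is not the default for
a structural reason: blurring contracts, and within a few iterations
merges, *any* two collapsed groups of points closer than `D`, so distinct
likelihood modes separated by less than the neighborhood radius are
systematically fused. With the recommended `D = 0.6` the permutation modes
of the four-peak benchmark sit 0.4–0.9 apart in normalized units depending
on the run phase, and only the fixed-data iteration recognizes them as
separate clusters while keeping the analysis count low. Both iterations
are verified against independent brute-force reference implementations.

Working ranges: `D = 0.5`–`0.6` (too small fragments the ensemble into
many tiny clusters whose scales are meaninglessly small; too large lumps
modes and the analysis is invoked often without helping) and
`ell = 0.1`–`0.2`; defaults `D = 0.6`, `ell = 0.2`.

# Synthetic benchmarks

No reference spectra are redistributed with the package; two generators
emulate the *statistical structure* of the canonical hard cases and are
labelled synthetic throughout.

**Four peaks** (`four_peaks_spec()`): a 200-channel Poisson spectrum of
four identical-width Gaussian peaks on a flat background — the likelihood
has exactly $4! = 24$ permutation-degenerate maxima (verified in the tests
by hill-climbing from all 24 permutations and finding 24 distinct,
equal-height optima). Defaults: positions $\{25, 80, 135, 190\}$, areas
$\{850, 300, 1300, 750\}$, $w = 8$, $bg = 2$ (about 3600 total counts, a
modest-statistics spectrum); prior box: each position uniform over the
full channel range (which is what makes the permutation degeneracy exact),
areas $U(0, 1.3\max A)$, $w$ within a factor ~2.5 of truth,
$bg \in [0,5]$. Beyond mode separability (next paragraph), the width and
area scales were chosen so the position basins are wide enough for the
walk to stay efficient while the area dimensions are still only partly
constrained — the regime in which a spectrum with very narrow, very weak
peaks drives the sampler into long marginal-acceptance stretches.

The positions and areas were *designed*, before any sampling experiment,
around the cluster-resolution condition: with live-range normalization a
transposition of peaks $i,j$ displaces two position and two area
coordinates, so the distance between the corresponding modes is
$\sqrt{2}\,\sqrt{\Delta\hat x_{ij}^2 + \Delta\hat A_{ij}^2}$, which must
exceed the neighborhood radius `D = 0.6` with margin for *every* pair,
including a ~25% allowance for mid-run live-range inflation. Evenly spread
positions give all non-adjacent pairs large position separation; the area
ordering $\{0.55, 0, 1, 0.45\}$ (in span units) hands the three
adjacent-position pairs area gaps $\ge 0.55$, for a worst-case
span-normalized mode distance of ~0.9. Early in a run, before the area
dimensions are constrained, the modes still overlap and the analysis
reports fewer, broader clusters — the expected and observed behavior; the
late-stage analyses resolve the permutation structure. Because the modes
are *exactly* degenerate, their populations perform neutral drift under
the discard/replace dynamics (births follow the random walk start, deaths
the global worst point, both proportional to population), and over the
long final tail a few of the 24 can starve; a late-stage cluster analysis
therefore typically reports 21–24 clusters, each containing a single
permutation class. The acceptance suite measures exactly this.

**Modulated decay** (`mod_decay_spec()`): a unit-binned Poisson series
from the modulated-decay model (midpoint rule for the bin integral; the
bins are narrow), with defaults ($C = 40$, $\tau = 15$,
$a_{\mathrm{mod}} = 0.25$, $\omega = 1$, $\varphi = 1$, $bg = 0.5$, 100
bins, ~600 counts) that make the $(a_{\mathrm{mod}}, \omega, \varphi)$
posterior beat-degenerate and multimodal.

What passing tests on these generators do *not* show: real spectra carry
instrument response, non-flat backgrounds, and calibration uncertainty
none of which are modelled here; the generators exercise the sampler, not
detector physics.

# Numerical choices and problem sizes

* Evidence, weights and normalizations: log space throughout;
  `logsumexp` accumulation; weighted quantiles from the smallest sample
  with cumulative weight $\ge p$.
* Degenerate inputs: empty spectra, non-increasing channels, negative
  counts, non-positive uncertainties, ragged files are all rejected with
  located errors; an all-`-Inf` initial live set is an initialization
  error.
* Reproducibility: everything (engine included) draws from R's RNG;
  `ns_fit(seed =)` derives per-run sub-seeds, and a full `run_experiment()`
  is byte-identical given the same config and seed (outputs carry no
  timestamps).
* The test-suite problem sizes are deliberately modest so the whole suite
  runs on one CPU in minutes: toy evidences use $K = 400$–$500$ with 16
  repeats, the four-peak structural checks use the reference setting
  $K = 2000$ once, and the uncertainty-scaling law is measured on a
  scaled-down two-peak sibling of the benchmark (2 permutation modes) over
  $K \in \{125, 250, 500, 1000\}$ with 12–24 repeats per point — the
  same $\delta(\ln E) \propto K^{-1/2}$ law at a fraction of the cost of
  the four-peak grid. With many exchangeable modes the law holds only once
  $K$ is large enough to explore all of them (roughly $K \ge 500$ for the
  24-mode problem, which `validate_ns_config()` warns about); the two-peak
  sibling keeps every grid point inside the valid regime.

# Known limitations

* The deterministic shrinkage ignores the stochasticity of $X_m$; the
  repeat-run scatter $\delta(\ln E)$ absorbs it in practice, and typically
  exceeds $\sqrt{H/K}$ by a modest factor.
* Without cluster recognition the global step scale never adapts to narrow
  well-separated modes (it stays at the inter-mode distance), so the walk
  acceptance decays in proportion to the shrinking contour width and a
  non-clustered run cannot reach a tight termination tolerance in bounded
  time on such problems — the sharpest illustration of why the cluster
  stage exists. The with/without-clustering consistency check in the test
  suite therefore runs both arms to a shared coarser tolerance
  (`stop_tol = 0.05`), where the truncation cancels from the comparison.
* The jump-counting walk carries the boundary-layer systematic described
  above; use `walk_unit = "proposals"` when absolute evidence accuracy at
  the $\sqrt{H/K}$ level matters.
* Exactly degenerate modes starve by neutral drift over very long runs;
  population-balancing between clusters is deliberately *not* implemented
  (the search must remain unbiased with respect to the posterior).
* Mean shift costs $O(K^2)$ per analysis; for $K \lesssim 10^4$ this is
  acceptable, and the consecutive-failure trigger keeps the number of
  invocations small.
* One dataset per fit; joint multi-dataset models with shared parameters
  are out of scope.
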