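---
title: "Anticipating stochastic trends with a two-timescale circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anticipating stochastic trends with a two-timescale circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendcircuit)
```

## The problem

A purely random environment cannot be predicted: if successive changes are
independent with zero mean, no mechanism beats a coin flip. Real
environments, however, carry momentum — nutrient gradients, temperature
drifts, and chemical plumes trend, and a trend that has been rising is more
likely to keep rising. A cell whose biochemistry estimates that momentum
gains a head start on its physiology. This package studies the smallest
circuit that makes such an estimate: two species, each a production–decay
balance against the same environmental input, differing only in timescale.
The fast species tracks the environment closely; the slow one remembers its
recent past; their difference measures the current trend and its sign
predicts the next direction of change. Financial technical analysis makes
the identical calculation under the name MACD (moving average
convergence–divergence), which is why the two reference parameterizations
below behave like a tight-band and a wide-band MACD.

## The input process and its accuracy ceiling

`make_trend_input()` composes three stages, all parameterized by
`trend_input_config()`:

1. **Random walk.** A Wiener process with diffusion scale 0.2 sampled every
   0.1 time units (`simulate_random_walk()`), so increments are i.i.d.
   Gaussian with variance $0.2^2 \times 0.1 = 0.004$. Sampling a
   continuous-time walk at fixed steps loses nothing: the discrete
   increments are exact.
2. **Normalization.** Each realized sequence is affinely mapped onto
   $[0.25, 0.75]$ (`normalize_affine()`). The map has positive slope, so it
   never flips an increment's sign and therefore never changes any
   sign-based statistic; it only standardizes the level and scale that the
   circuit sees, keeping the input in a plausible "concentration-like"
   band bounded away from zero. A constant sequence has no well-defined
   map and raises an error rather than silently filling in a midpoint,
   because a silent fill would corrupt accuracy statistics downstream.
3. **Exponential smoothing.** The recursion
   $u_t = (1-m)\,\hat u_t + m\,u_{t-1}$ (`ema_smooth()`) with memory
   $m \in [0, 1)$, initialized at the first sample to avoid a startup
   transient. Smoothing constants are quoted under two conventions in the
   time-series literature (weight on the new observation vs. weight on the
   previous average); this package always means *weight on the previous
   smoothed value*, and `memory_from_delta()` converts a constant quoted
   the other way. The reproduction preset uses $m = 0.8$.

Differencing the smoothing recursion shows why this input is predictable:
$\Delta u_t = (1-m)\Delta\hat u_t + m\,\Delta u_{t-1}$, an AR(1) process in
the increments with coefficient exactly $m$. Since the prior increment is
the only information about the next one, the best possible predictor is
"the next change continues the last change", and its hit rate is the
orthant probability of a bivariate normal with correlation $m$:

$$\Pr(\text{sign match}) = \tfrac12 + \frac{\arcsin m}{\pi},$$

implemented as `theoretical_sign_match()`; at $m = 0.8$ it equals
$0.7952$. `sign_persistence()` measures the same quantity empirically, and
the test suite verifies both the AR(1) autocorrelation and the convergence
of the empirical rate to the formula at $10^5$ samples. Pairs containing an
exact-zero increment are excluded from numerator and denominator — a
measure-zero event under continuous noise that nevertheless needs a
deterministic rule for constructed inputs.

## The circuit and its exact integration

The circuit is the linear system

$$\dot x = \alpha u - \beta x, \qquad \dot y = \gamma(\alpha u - \beta y),$$

with production gain $\alpha$, decay rate $\beta$, and timescale ratio
$\gamma$. Under constant input $c$ both states settle at the shared
equilibrium $\alpha c/\beta$ regardless of $\gamma$; with $\gamma < 1$ the
slow state $y$ approaches it more slowly, so the momentum $d = x - y$ is
positive while the input rises. Because the system is linear, rescaling
the input rescales $(x, y, d)$ exactly and leaves every sign-based
statistic unchanged.

Between samples the input is taken as piecewise linear (the same
interpolation contract as `interpolate_series()`). On a segment where
$u(\tau) = a + b\tau$, the ODE $\dot z = g(a + b\tau) - kz$ has the
closed-form solution

$$z(\Delta t) = \bigl(z_0 - P(0)\bigr)e^{-k\Delta t} + P(\Delta t), \qquad
P(\tau) = \frac{g}{k}(a + b\tau) - \frac{g\,b}{k^2},$$

implemented in `segment_solution()` and chained across segments by
`integrate_circuit()` (the chaining is a first-order linear recurrence,
evaluated at C speed by `stats::filter()`). The trajectory therefore
carries **no integration error**: accuracy statistics reflect the model,
not a step size. The test suite cross-checks the closed form against
numerical quadrature of the driven-decay integral and the chained
integrator against a brute-force explicit-Euler run at step $5\times
10^{-7}$, agreeing to $10^{-6}$ over 100 randomized configurations.

Two cosmetic-but-deterministic conventions: the scaled momentum
$s = 1000[\sigma(d) - 0.5]$ (logistic $\sigma$) is reported for plotting
only — it is odd, strictly increasing, and bounded by 500, so predictions
use `sign(d)` directly; and an exact tie $d = 0$ carries the previous
prediction forward, with a leading tie defaulting to $+1$
(`predict_direction()`).

## Scoring

`circuit_accuracy()` aligns predictions and outcomes as follows: the
prediction at sample $t$ (the sign of $d_t$) targets the realized increment
$u_{t+1} - u_t$; the final sample yields no prediction. The realized
ceiling — `sign_persistence` restricted to the same index range — is
computed on the same window, so the reported deviation is a paired
difference, not a difference of statistics over mismatched windows. The
first 20 samples are excluded by default (`burn_in`); initialization is at
the equilibrium of the first input value, so the transient is already
small, and the burn-in removes what remains.

`ensemble_evaluate()` repeats this over independent sequences, with
sequence $i$ seeded as `seed + i` so the whole ensemble is a pure function
of the master seed. The default experiment scale is 200 sequences of 1,000
samples: large enough that the median deviation is stable to well under
the tolerances quoted below, small enough that the full evaluation runs in
seconds on one core.

## Time scaling

The sampled input carries no intrinsic unit of model time, so the rates
$(\alpha, \beta, \gamma\beta)$ only acquire meaning once each inter-sample
interval is assigned a duration, `time_per_sample`. The two reference
parameter sets shipped as `preset_params()` were derived under a scaling
the package had to calibrate: with one model time unit per sample they are
far too slow to track the preset input (median deviation ≈ 0.27). A single
scaling must make both regimes behave as documented — the accuracy set
(0.1663, 0.08314, 0.2782) tracking the ceiling to ≈ 0.001 and the robust
set (0.4179, 0.009483, 0.2587) lagging it by ≈ 0.12 — and
`time_per_sample = 100` is the round value that satisfies both constraints
simultaneously (neighbouring scales fail at least one). It is the package
default; under it the fast state relaxes essentially within one sample
($e^{-\beta\,\mathrm{d}t} \approx 2\times 10^{-4}$ for the accuracy set)
while the slow state retains $e^{-\gamma\beta\,\mathrm{d}t} \approx 0.1$
of its memory per sample. Users fitting their own rates should choose the
scaling that matches their system's sampling cadence.

## Optimization

`run_optimization()` tunes $(\alpha, \beta, \gamma)$ by Nelder–Mead over
the *logarithms* of the parameters, which enforces positivity without
constraints and equalizes step sizes across parameters spanning orders of
magnitude. The objective is evaluated on a fixed, seeded set of training
sequences (common random numbers), making it deterministic in the
parameters and the simplex search well-posed; non-finite evaluations
return the worst possible value so the simplex can recover. Five restarts
(the initial point plus seeded log-normal jitters, s.d. 0.75) guard
against the simplex collapsing in a flat region; defaults are 30 training
sequences, 300 iterations per restart, and a cold start at
$(0.1, 0.1, 0.5)$. The result reports the objective re-evaluated at the
optimum on the training seeds (exact, same sequences) and a median
deviation on held-out seeds, offset from the training seeds by
construction. Held-out and training accuracies agree to well under 0.02 at
this scale — with ~20,000 scored predictions per evaluation and only three
parameters, the optimizer has little room to overfit the noise.

The robustness-weighted objective adds `robustness_weight` times the mean
absolute momentum $|x - y|$ to the mean accuracy. This scalarization is
deliberately explicit and tunable, and it has a known degeneracy: accuracy
is invariant to scaling $\alpha$ (linearity), while the mean width grows
linearly in it, so with a large weight and unlimited iterations the
optimizer inflates $\alpha$ without bound. In practice the finite
iteration budget yields wide-band, lagging solutions of the intended kind;
a scale-invariant width (e.g. relative to $\alpha/\beta$) would remove the
degeneracy and is an obvious extension.

Nelder–Mead on this surface routinely finds parameter sets that reach the
ceiling as closely as the shipped accuracy preset but with different
coordinates — the objective has a ridge of near-equivalent optima (any
sufficiently fast $x$ paired with a suitably slower $y$), so the shipped
triples are reference points, not unique optima, and the test suite treats
them as fixed inputs rather than expected optimizer outputs.

## What the generator does and does not emulate

The synthetic input captures the essential structure of a trending
environment: Gaussian diffusion, bounded level, and exponentially-fading
memory with a known, tunable persistence. It omits features of real
environmental signals — heavy-tailed shocks, regime switches,
state-dependent volatility, measurement noise in the circuit itself, and
any feedback from the organism onto the environment. Passing tests
therefore certify the circuit's behaviour *for this process class*: the
AR(1) ceiling argument is exact only for Gaussian increments, and the
orthant-probability formula would change under other innovations. The
stochastic acceptance checks quantify agreement at the default scale (200
sequences × 1,000 samples) with tolerances of ±0.01 on the accuracy
ceiling and the accuracy-regime deviation and ±0.03 on the
robustness-regime deviation.

## Numerical conventions, degenerate inputs, limitations

- `memory = 1` (never update), non-increasing times, constant series fed
  to the normalizer, and `beta <= 0` or `gamma <= 0` (no stable
  equilibrium) are rejected with named errors.
- Interpolation and scoring stay strictly inside the sampled range: no
  extrapolation, and the final sample yields no prediction.
- All randomness flows through explicit integer seeds (`withr::with_seed`),
  so every generator, ensemble, and optimization is a pure function of its
  configuration; derived seeds are simple offsets documented in the
  function help.
- TSV exports print 15 significant digits so round trips preserve values
  to full printed precision; run manifests record the resolved
  configuration, package version, and seed for bit-identical reruns.
- The package deliberately excludes stochastic noise inside the circuit
  states, nonlinear production terms, and non-Gaussian walks; these are
  extension points, not supported options.
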