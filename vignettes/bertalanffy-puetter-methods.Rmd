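---
title: "Fitting Bertalanffy-Puetter growth models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting Bertalanffy-Puetter growth models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpgrowth)
```

## The model class

`bpgrowth` fits the two-exponent Bertalanffy-Puetter family of growth
models to longitudinal size-at-age data,

$$\frac{dv}{dt} = p\,v^a - q\,v^b, \qquad 0 \le a < b,\quad v(t_1) = v_0 > 0,$$

with $v$ a volume in mm^3 and $t$ a time in days. The exponent pair
$(a, b)$ indexes the family: each pair defines one model with three free
parameters $p$ (mm^3^(1-a)/day), $q$ (mm^3^(1-b)/day) and $v_0$ (mm^3).
Classical growth models are special pairs — exponential $(0, 1)$, von
Bertalanffy $(2/3, 1)$, Verhulst/logistic $(1, 2)$, the
generalized-Bertalanffy line $b = 1$ and the Richards line $a = 1$. The
diagonal $a = b$ obeys a different (Gompertz-type) differential equation
and is excluded throughout; the constructors enforce
$b - a \ge 10^{-6}$ so that the power-of-ratio formulas below stay well
defined.

For positive $p, q, v_0$ every curve is bounded and monotone towards the
equilibrium of the right-hand side, the *asymptotic volume*

$$v_\infty = (p/q)^{1/(b-a)},$$

and, when $a > 0$, the growth rate $p v^a - q v^b$ is maximal at the
*inflection volume*

$$v_\text{infl} = \left(\frac{a\,p}{b\,q}\right)^{1/(b-a)} < v_\infty.$$

These closed forms are not printed in most applied work but follow
directly from the differential equation; the test suite validates them
against a dense numeric scan of the growth rate and against the
integrated curve's long-time limit. Near-diagonal pairs can produce
astronomically large (yet double-representable) asymptotes such as
$10^{132}$ mm^3; these are legitimate fits that behave like unbounded
growth on any observable horizon, which is why both formulas are
evaluated in log space and overflow to `Inf` with a warning instead of
failing.

## Numerical integration

Solution curves have no closed form for general exponents, and the
fitted parameter ranges are brutal: the landscape sweep routinely visits
$b \approx 9$–$10$ with $q \approx 10^{-29}$–$10^{-34}$, where
$q\,v^b$ is a difference of enormous powers. Integrating the volume
directly overflows, so the package integrates the log-volume
$u = \ln v$,

$$\frac{du}{dt} = p\,e^{(a-1)u} - q\,e^{(b-1)u},$$

which keeps the state positive by construction and compresses the
dynamic range. The integrator (in C++, for the roughly $10^5$–$10^6$
curve evaluations per exponent pair that the stochastic fit needs) is an
adaptive Dormand-Prince 4(5) scheme with default tolerances
`rtol = 1e-8`, `atol = 1e-10` in log space, both configurable. A curve
is declared *failed* — never silently wrong — when the step budget is
exhausted, a term overflows, or $|u| > 200$; failed curves score an
infinite SSE, which the annealer simply rejects. The test suite
cross-checks the integrator against the logistic and
bounded-exponential closed forms (relative tolerance $10^{-6}$) and
against an independent stiff solver (`deSolve::lsoda`) on the same
log-space right-hand side, including the extreme
$(a, b) = (1.34, 8.83)$, $q \approx 10^{-29}$ regime.

Curves are anchored at the *first observation time* of the dataset being
fitted, $v(t_1) = v_0$; for the built-in tumor dataset $t_1 = 0$, so
anchor and calendar origin coincide. Evaluating a fitted curve on a
different time mesh (prediction bands, growth-rate envelopes) passes the
anchor explicitly via the `t0` argument of `solve_curve()`.

## Least squares for one exponent pair

For a fixed pair, the fit criterion is the plain sum of squared volume
errors

$$\mathrm{SSE}(p, q, v_0) = \sum_{i=1}^n \left(v_i - v(t_i)\right)^2,$$

and $\mathrm{SSE}_\mathrm{opt}(a, b) = \min_{p,q,v_0} \mathrm{SSE}$ is
the landscape value of the pair. Minimization combines three
ingredients:

1. **Multiplicative simulated annealing** (`anneal_fit()`): each step
   multiplies all three parameters by independent factors
   $e^{\sigma Z}$, $Z \sim N(0,1)$, with $\sigma = 0.05$ by default.
   Multiplicative proposals keep the parameters positive (hence the
   curves bounded) and are scale-free, which matters because optimal
   $q$ values span 30 orders of magnitude across the grid. Downhill
   moves are always accepted; uphill moves with Metropolis probability
   $e^{-\Delta \mathrm{SSE}/T}$. The temperature is calibrated from
   probe proposals so the initial uphill acceptance is about 0.3, the
   chain restarts from the best-seen parameters every 1,000 steps, and
   at each restart the temperature is cooled adaptively (factor 0.9
   when the recent uphill-acceptance rate exceeded 20%, otherwise
   0.97). Cold starts use 50,000 steps from $p = q = 1$,
   $v_0 = v_1$; warm starts (from a neighboring grid pair's optimum)
   use 10,000. All randomness flows through R's RNG, so a seeded
   configuration reproduces bit-identical fits.
2. **Levenberg-Marquardt polish** (`polish_fit()`, via
   `minpack.lm::nls.lm`): a deterministic local refinement in
   log-parameter space $(\ln p, \ln q, \ln v_0)$, which preserves
   positivity implicitly and conditions the tiny-$q$ regimes where
   raw-scale derivatives degenerate. The polish never returns a worse
   SSE than its start.
3. **Deterministic multistart safeguard** (inside `fit_pair()`): a
   small family of data-driven starts — $v_0 = v_1$, carrying capacity
   guessed as $\{1.1, 1.5, 3, 10\} \times \max v_i$, and $p$ chosen so
   the model's initial relative growth rate matches the first observed
   inter-point rate — each polished by Levenberg-Marquardt.

The third ingredient is a deliberate design addition. The SSE surface
of a far-from-diagonal pair contains a vast, nearly flat plateau of
fast-relaxing curves (every $(p, q)$ with the same equilibrium and a
relaxation time shorter than the sampling interval produces the same
near-constant trajectory). A cold annealing chain started at
$p = q = 1$ lands on this plateau and must diffuse across several
decades of parameter space to reach the growth-curve basin; within any
realistic step budget it frequently fails to, regardless of the cooling
schedule. The published optima for this model family were produced by
warm-starting along the grid, which sidesteps the plateau; a standalone
single-pair fit has no such neighbor, and the heuristic starts restore
robustness at the cost of a few hundred curve evaluations. With them,
`fit_pair()` reproduces all published per-pair optima of the tumor
dataset to three or four significant digits, from any seed.

SSE values are conventionally reported to 5 significant digits;
comparisons against published optima in the tests use a 1% relative
tolerance.

## The landscape over the exponent grid

`sweep_grid()` visits the lattice $a = m \cdot s$, $b = a + n \cdot s$
(default spacing $s = 0.01$; tests and examples use coarser lattices)
with an outer loop over $a$ and an inner loop over increasing $b$,
cold-starting each row at $(a, a + s)$ and warm-starting every
subsequent pair from its left neighbor's optimum. Warm starts both
accelerate the sweep and stabilize it — the optimum moves continuously
along $b$. The default initial region, $0 \le a \le 2.1$,
$a < b \le 3.1$, is a rectangle covering all named models; it is a
package choice (the historical search region was drawn as a polygon
around the named pairs, which is not recoverable exactly), and both the
rectangle and an optional `region_mask` predicate are configurable.

When the best pair lands on the grid's upper or right boundary,
`extend_if_boundary()` enlarges the rectangle by 0.5 in the touched
direction and fits the new pairs (warm-started from the nearest fitted
entries), repeating until the optimum is interior or the hard caps
$a \le 4$, $b \le 12$ are reached — the caps cover the most extreme
published segment optima ($b \approx 10.4$) while bounding runtime. If
a cap is hit, the landscape is flagged `secured = FALSE` ("optimality
not secured"), mirroring how the boundary case must be reported rather
than hidden.

Near-optimal regions — all pairs whose SSE exceeds the minimum by at
most 1, 5 or 10% — quantify how sharply the data identify a model; the
regions nest by construction and always contain the argmin (ties broken
lexicographically). `landscape_smoothness()` screens the
well-conditioned zone $a, b \le 3$ for entries deviating from their
neighbor median by 50% or more; such "frayed" entries indicate a
stalled stochastic fit and can be retried automatically with a 5x
budget (`retry_frayed = TRUE`). Landscape tables serialize to CSV in
`%.17g` precision so that round trips preserve 15+ significant digits
even for $q \sim 10^{-34}$.

## Prognosis from initial segments

`fit_segment()` truncates the series at a cutoff (the conventional
cutoffs for the built-in dataset are 65, 76, 87, 98 and 107 days),
sweeps the grid on the segment (with boundary extension — segment
optima often run to very large $b$), and evaluates the winning curve on
*all* observations without refitting (`extrapolation_sse()`). Segments
keeping fewer than 4 observations are refused: the model class
effectively spends 5 degrees of freedom. Two inequalities are
structural and tested: the all-data SSE of a segment fit is at least
its segment SSE (residuals over a superset), and the refitted full-data
optimum is at least as good as any extrapolated segment fit on the same
points.

`horizon_assessment()` condenses the extrapolations into a feasible
forecast horizon: for each segment, the longest time beyond the cutoff
over which the relative prediction error at every intermediate observed
point stays below a tolerance, summarized by the median across
segments. The default tolerance of 15% relative volume error is a
package choice — the underlying analyses report only the qualitative
verdict that prognosis beyond roughly ten days (one observation
interval) was poor — and it is exposed as an argument and CLI flag.
On the built-in data the default settings indeed produce a horizon of
about one inter-observation interval.

## Diagnostics

* `residual_report()`: residuals $v_i - v(t_i)$, their SD (denominator
  $n - 1$), a two-sided sign test for median 0, and Anderson-Darling /
  Cramer-von-Mises normality tests. The tests are the *composite*
  variants (mean and SD estimated from the sample, via the nortest
  package); for residuals of a fitted curve a fully-specified null is
  not defensible. They require $n \ge 8$ and are reported `NA` below
  that.
* `spline_interpolate()` / `spline_rgr()`: natural cubic spline through
  the observations (zero second derivative at the ends; the boundary
  condition is configurable to `"fmm"`) and the model-free relative
  growth rate $s'(t)/s(t)$ it implies. The natural choice is the
  package default because it is the canonical "textbook" spline and
  keeps the interpolant conservative at the ends; tests verify
  exactness at the knots and agreement with an independently coded
  tridiagonal natural-spline solver.
* `rgr_envelope()`: pointwise minimum/maximum of the model relative
  growth rate $v'/v = p v^{a-1} - q v^{b-1}$ across all near-optimal
  pairs of a landscape — the model-uncertainty band around the growth
  history. Envelopes collapse at threshold 0 and widen monotonically
  with the threshold.
* `prediction_band()`: delta-method single-observation band,
  $\hat v(t) \pm t_{n-3}\, s \sqrt{1 + h(t)}$ with
  $s^2 = \mathrm{SSE}/(n-3)$ and leverage $h$ from the
  finite-difference Jacobian of the curve with respect to the
  log-parameters. The method is a package choice (any of several
  standard nonlinear-regression bands could be used); accordingly the
  tests assert only structural properties (collapse at zero residual
  variance, monotonicity in the confidence level) and a loose coverage
  check — over 200 seeded synthetic replicates at the best-fit curve,
  at least 90% of observations fall inside the nominal 95% band. The
  small-sample $t$ approximation makes exact coverage claims
  inappropriate.

## The synthetic-data generator

`generate_synthetic()` samples an exact model curve at given times and
adds independent Gaussian noise, truncating at a small positive floor
(with a warning when more than 10% of points are truncated) and
recording the generating parameters in an attribute. The
parameter-recovery experiments in the test suite emulate the study
conditions of the built-in dataset: 14 observations over 114 days from
the tumor-like best-fit curve, with noise SD of 5% of the maximal
volume (about 175 mm^3, comparable to the 99 mm^3 residual SD of the
real fit) for the noisy-recovery check, and 20 fixed seeds. What the
generator deliberately does *not* emulate: measurement error growing
with volume (the lognormal error family), serial correlation between
measurements, or digitization rounding. Passing recovery tests
therefore demonstrate correctness of the estimation machinery under the
stated error model, not robustness to those real-data features.

## Problem sizes and determinism

The documented full budgets (50,000/10,000 annealing steps, spacing
0.01) reproduce the published analysis; the test suite exercises the
identical code paths at reduced scale, chosen so the whole suite runs
in a few minutes: `fast_factor` 10–50 for annealing budgets, grid
spacings 0.1–0.5, and the full budgets only for the handful of
headline single-pair fits. The acceptance script fits three exponent
pairs at full budget on the 7- and 14-point datasets. Every stochastic
component draws from R's RNG under a single seed, so any reported
number is exactly reproducible; thanks to the deterministic polish and
multistart safeguard, the headline fit results are stable across seeds
to far better than the published precision.

## Known limitations

* No global-optimality guarantee for a single pair: the contract is
  monotone improvement, seeded reproducibility, and agreement with the
  published optima within tolerance.
* The Gompertz-type diagonal $a = b$ and lognormal (weighted) error
  models are out of scope, as is information-criterion model selection
  — within this family, added parameters are fixed exponents, not
  fitted quantities, so SSE comparison across pairs is the intended
  use.
* Near-diagonal and large-$b$ pairs are intrinsically ill-conditioned;
  the package mitigates (log-space integration and optimization,
  full-precision serialization, smoothness screening) but cannot
  remove the ill-conditioning, which is a property of the model family
  itself.
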