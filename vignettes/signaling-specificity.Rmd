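---
title: "Methods: steady-state specificity in pathways that share a component"
author: "sigspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state specificity in pathways that share a component}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigspec)
```

## The model and its assumptions

`sigspec` studies a deliberately minimal caricature of signaling
crosstalk: two pathways, X and Y, whose inputs `x0` and `y0` both feed a
shared intermediate `x1`, which in turn produces the two outputs `x2` and
`y2`. Mass-action production and first-order decay give

$$\dot x_1 = a_1 x_0 + b_1 y_0 - d_1 x_1,\qquad
  \dot x_2 = a_2 f^X(x_1) - d_{2x} x_2,\qquad
  \dot y_2 = b_2 f^Y(x_1) - d_{2y} y_2.$$

Assumptions worth keeping in mind:

* **Steady state only.** All indicators are ratios of steady-state
  outputs. Transient or pulsed inputs can behave qualitatively
  differently and are out of scope.
* **Exclusive inputs.** A network is probed under "X on"
  ($x_0 > 0, y_0 = 0$) or "Y on" ($x_0 = 0, y_0 > 0$), never both at
  once. Simultaneous stimulation poses a different (signal-integration)
  question.
* **Lumped components.** Each variable may stand for a whole receptor
  complex or cascade tier; inactive precursors are not tracked, so the
  natural initial condition for integration is the all-zero (all
  inactive) state.
* **Monotone activation.** `fX`, `fY` are monotone non-decreasing:
  identity (the weakly-activated, effectively linear regime), Hill
  $f(u) = u^n/(u^n + \varepsilon^n)$ with exponent 1 (hyperbolic) or
  $> 1$ (ultrasensitive), or any user-supplied monotone function.
  Units are arbitrary but consistent; thresholds are concentrations,
  decay rates inverse times.

The degree of ultrasensitivity has a concrete dose-response meaning:
`hill_fold_change(n)` returns the input fold-change that moves the output
from 10% to 90% of maximum, $81^{1/n}$ — 81-fold for a hyperbolic
response, 9-fold at $n = 2$, 3-fold at $n = 4$.

## Indicators

With `X|X` denoting the steady-state X output under X input and so on,

$$S_X = \frac{X|X}{Y|X},\quad S_Y = \frac{Y|Y}{X|Y},\quad
  F_X = \frac{X|X}{X|Y},\quad F_Y = \frac{Y|Y}{Y|X},$$

and the composites are minima: $MS = \min(S_X, S_Y)$,
$MF = \min(F_X, F_Y)$, $MFMS = \min(MS, MF)$. Ratio conventions: a
positive numerator over a zero denominator is $+\infty$ (a pathway with
no crosstalk has unbounded specificity — this keeps the
scaffolding limit $D \to 0$ well defined), while $0/0$ raises an error,
because it signals a degenerate network rather than a numerical accident.
Minima follow extended-real ordering.

Because real outputs are measured in incomparable units, the package also
offers a diagonal normalization (each column of the quartet divided by
its cognate output `X|X` or `Y|Y`), under which
$\hat S_X = \hat F_Y$ and $\hat S_Y = \hat F_X$ hold exactly and
specificity and fidelity collapse into one notion. Normalization is
opt-in (`normalized_indicators()`), since the right characteristic level
is system-specific; with it, mutual specificity inherits the hardness of
mutual fidelity and becomes impossible without cross-regulation.

## What can and cannot be achieved

Two structural facts anchor everything else:

* **Mutual fidelity is impossible in the basic architecture.** At steady
  state `x1` takes one value under X input and another under Y input;
  monotone activation then forces both outputs to be larger under
  whichever input gives the larger `x1`, so one of $F_X$, $F_Y$ is
  $\le 1$. This argument uses only monotonicity, which is why the test
  suite exercises it with linear, hyperbolic, ultrasensitive and random
  piecewise-linear monotone activations alike.
* **Mutual specificity is achievable with curved (hyperbolic or
  ultrasensitive) activation** even without insulation, by placing the
  two activation thresholds on either side of the two `x1` steady
  states. For the hyperbolic limits this requires
  $1 < \alpha/\beta < \varepsilon_X/\varepsilon_Y$ — the package
  verifies the orientation of this regime numerically in its tests
  rather than trusting any printed chain of inequalities, and a worked
  parameter set in the metrics tests exhibits $MS > 1$ with $MF \le 1$.

## Insulating mechanisms and the cross-regulatory term

Each mechanism adds one ingredient, and one dimensionless number (the
CRT) measures how much cross-regulation it supplies:
$\alpha/\varepsilon_g$ for cross-pathway inhibition, $1/k_{\rm leak}$
for combinatorial signaling, $d_1/D$ for
scaffolding/compartmentalization (requiring $D_{in} = D_{out}$ and equal
pool decay rates — asymmetric exchange is representable in the model but
has no single CRT). Comparing mechanisms at matched CRT is what makes
the bounds below meaningful.

At fixed CRT the attainable MFMS is:

| mechanism | linear activation | ultrasensitive activation |
|---|---|---|
| CPI | 1 | $1 + CRT$ |
| CS  | $\sqrt{CRT}$ | $CRT$ |
| SC  | $1 + CRT$ | exact symmetric formula below |

Two of these deserve comment.

**Linear CS.** The linear-activation CS network has
$MFMS = \min\{\alpha/\beta,\ (\beta/\alpha)CRT,\ (x_1^X/x_1^Y)CRT,\
x_1^Y/x_1^X\}$. The optimum over the two free ratios is the geometric
mean: each pair $\min(r, CRT/r)$ peaks at $\sqrt{CRT}$. `mfms_bound()`
therefore returns $\sqrt{CRT}$, and the test suite confirms it twice
over — once against a direct maximization of the min-expression and once
against the full-network optimizer (`maximize_mfms()`), which lands on
the same value. We chose to trust this doubly-verified optimum over any
single printed expression for this case.

**Symmetric SC.** Under the symmetric reduction pinned in
`sc_symmetric_network()` ($d_1 = 1$, $D = 1/CRT$,
$a_1 x_0 = b_1 y_0 = a$, $\alpha = \beta = 1$,
$\varepsilon_X = \varepsilon_Y = 1$, $n = m$) the anchored pool is
$x_{1N}|X = a(1+CRT)/(2+CRT)$ and all four indicators coincide, giving
the *exact* value

$$MFMS = \frac{a^n (1+CRT)^n + (1+CRT)^n (2+CRT)^n}
              {a^n (1+CRT)^n + (2+CRT)^n} \sim (1+CRT)^n .$$

This is the only mechanism whose CRT and ultrasensitivity compound
multiplicatively: MFMS grows super-linearly in CRT whenever $n > 1$
(the tests check strict convexity on a CRT grid), and both exponents can
be raised to benefit. The formula decreases in $a$, approaching
$(1+CRT)^n$ as $a \to 0$; when the package quantifies "SC beats CPI/CS
by an order of magnitude at $n = 2$, CRT = 10", it therefore compares
the CPI/CS bounds against the symmetric SC value maximized over $a$
(121 vs 11 and 10), not against one arbitrary input strength.

## Derivative-sign analysis

Which pathway should become more switch-like? `derivative_signs()`
differentiates each indicator with respect to the Hill exponents,
treating them as continuous. Signs — not magnitudes — are the object of
interest, so the implementation uses central finite differences on the
closed-form steady-state indicators with base step
$h = \max(10^{-4}, 10^{-4} n)$, repeats at $h/2$, and reports a sign
only when the two estimates agree; disagreement or magnitude below
$10^{-7}(1 + |{\rm indicator}|)$ is reported as `"zero"`. Genuine zeros
exist (a pool exactly at its threshold gives a Hill value of 0.5 for
every exponent; $F_X$ has no $m$-dependence under CS), and deep Hill
saturation can push a true derivative below numerical resolution — the
function reports that honestly rather than guessing a sign.

For single-pool mechanisms the specificity signs obey exact threshold
conditions (e.g. $\partial S_X/\partial n > 0 \iff x_1^X >
\varepsilon_X$), and combining all favorable conditions produces a
cyclic, unsatisfiable chain — so CPI can exploit only $n$ (its regime is
$\varepsilon_Y < x_1^Y < \varepsilon_X < x_1^X$) and CS only $m$. With
scaffolding the conditions split pool-wise into two genuine intervals,
`mutual_benefit_feasible()` reports them with witnesses, and both
exponents can help simultaneously.

## Numerical choices

* **Analytic solver first.** The cascade is feed-forward, so steady
  states resolve in closed form (a scalar for `x1`, a 2-by-2 linear
  solve for the scaffold pools); the CPI inhibition factor is applied
  with the already-resolved `x2`. These closed forms are exact zeros of
  the right-hand side (tested to $10^{-12}$).
* **ODE integration as oracle.** `steady_state_numeric()` exists to
  check the closed forms, not to replace them: `lsoda` (stiff-capable)
  from the all-zero state, `rtol = 1e-12`, `atol = 1e-14`, outputs on a
  log-spaced time grid spanning eight decades up to `t_max` (default
  $10^6$). Convergence is declared when
  $\|\dot x\|_\infty < {\rm tol}\,(1 + \|x\|_\infty)$ with default
  `tol = 1e-10`; the solver returns the *latest* converged snapshot,
  because small-magnitude components keep settling in relative terms
  after the residual test first passes. Non-convergence raises an error
  rather than returning a truncated state. Agreement with the analytic
  path is tested at $10^{-6}$ relative error over randomized networks of
  all four mechanisms.
* **Hill evaluation.** Computed via $(u/\varepsilon)^n$ so large inputs
  saturate to 1 instead of overflowing.

## The sweep engine as synthetic-data generator

There are no external data in this problem: the Monte-Carlo sweep *is*
the data generator, emulating an ensemble of plausible networks. Its
defaults are the study conditions used throughout the package:

* decay rates and inputs fixed at 1, so the sampled dimensionless ratios
  `a1/d1`, `b1/d1`, `a2/d2x`, `b2/d2y` are the parameters themselves;
* per-mechanism ranges: `a1/d1` in $[1,5]$ and `b1/d1` in $[0.1,1]$ for
  CPI (the X input is the favored one), mirrored for CS, both strong for
  SC; output ratios in $[0.1, 5]$ for all;
* $\varepsilon_X = 1$ fixed (the concentration unit);
  $\varepsilon_Y$ sampled log-uniformly over $[0.01, 10]$ — a
  three-decade range calls for a log law, while the single-decade rate
  ratios are sampled uniformly on a linear scale (both laws are config
  options);
* the cross-regulation parameter pinned at CRT = 10 by default ("held
  constant and sufficiently high" while exponents vary), or sampled over
  $[0.01, 100]$ ($[1, 100]$ for CS) when freed;
* common random numbers: each trial's draws are a deterministic function
  of `(seed, draw_index)` and are reused across the whole exponent grid,
  so percentile curves vary smoothly in the exponent;
* percentile summaries use the nearest-rank definition with $+\infty$
  ranked above every finite value; degenerate draws are dropped and
  counted, never fatal.

At 1,000 trials per grid point the 90th-percentile curves reproduce the
mechanism-specific preferences: CPI rises in $n$ and is flat in $m$; CS
rises in $m$; SC rises dramatically when both exponents grow together
(well past MFMS = 100 by $n = m = 10$). One empirical subtlety: the CS
curve against $n$ is not merely flat but *decreasing* under these
ranges — raising $n$ drives $F_X = CRT \cdot f^X(x_1^X)/f^X(x_1^Y)$
toward zero because $x_1^X < \varepsilon_X < x_1^Y$ in the CS regime.
The package's tests therefore read "flat" as "does not substantially
increase", which is the claim with scientific content (only the cognate
exponent helps).

What the generator does **not** emulate: molecular noise (deterministic
ODEs only), explicit enzyme-substrate mechanisms or scaffold occupancy
dynamics, correlated parameters, time-varying inputs, or simultaneous
stimulation. Passing sweep tests therefore says the *steady-state
deterministic* comparisons hold across a broad random ensemble — not
that real, stochastic, transient networks behave identically.

## Sharpness verification

`maximize_mfms()` checks that the closed-form bounds are attainable:
random multi-start search (log-uniform over four decades per magnitude;
exponents up to 10) followed by Nelder-Mead refinement of the best
starts, at pinned CRT. With a budget of ~1,000 starts it reaches the
CPI/CS ultrasensitive bounds and the linear SC bound to well within 10%,
and never exceeds any bound — both directions are asserted for CRT in
{1, 3, 10}. The ultrasensitive SC search is restricted to the symmetric
family, where the exact formula provides the comparison value. The
search is statistical, not a global-optimization guarantee; that is all
sharpness verification requires.

## Problem sizes

The shipped tests use: 1,000-trial sweeps per grid point for the
percentile curves; a 10,000-draw sweep plus 2,000-start refinement for
the linear-CPI maximum; 500 randomized networks for the
analytic-vs-numeric solver comparison; 1,000 randomized monotone
networks for the mutual-fidelity impossibility property. The full suite
runs in about a minute on one CPU; `scripts/acceptance.R` in under ten
seconds.

## Known limitations

* The CRT is defined only for symmetric exchange and pool decay in SC;
  asymmetric scaffolds have no single cross-regulation scale here.
* Bi-directional insulation (e.g. CPI in both directions, or CPI
  combined with CS) is not modeled.
* Basal (input-free) activity is absent, so normalization by basal
  levels — an alternative to the diagonal normalization — is not
  offered.
* `k_leak = 0` and `D = 0` produce infinite indicators by design; code
  consuming sweep records should expect `Inf` (the percentile machinery
  does).
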