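---
title: "Transient cell-size dynamics under a size-proportional division rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient cell-size dynamics under a size-proportional division rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmsize)
```

## The model and its assumptions

`crmsize` treats bacterial division as a continuous-time stochastic
process rather than a discrete map between birth and division sizes. A
cell grows exponentially, $ds/dt = \mu s$, $s(0) = s_0$, and divides with
an instantaneous rate (splitting rate function) proportional to its
current size,
$$h(t) = k\,s(t) \qquad \text{(generalized } h = k\,s^\lambda\text{)},$$
halving exactly at each division. The assumptions are therefore:
exponential single-cell growth at a common, noise-free rate $\mu$;
divisions as a single-step event with hazard $h$; perfectly symmetric
partitioning; and, for ensembles, a fixed population in which one
daughter is kept per division (the mother-machine observation scheme).

Because the size after $n$ divisions is $s(t) = s_0 e^{\mu t}/2^{n(t)}$,
the model is fully described by the division-counting process $n(t)$,
whose master equation is
$$\frac{dP_0}{dt} = -k s_0 e^{\mu t} P_0, \qquad
\frac{dP_i}{dt} = \frac{k s_0 e^{\mu t}}{2^{i-1}} P_{i-1}
  - \frac{k s_0 e^{\mu t}}{2^{i}} P_i,$$
with $P_i(0) = \delta_{i,0}$. At $\lambda = 1$ the cumulative hazard of
one cycle inverts in closed form, and the size added per cycle is
exponential with mean $\bar\Delta = \mu / k$ independent of birth size:
the adder strategy, with added-size noise $CV^2_\Delta = 1$. (An
exponential added-size density is sometimes written with separate scale
symbols in its prefactor and exponent; normalization forces both to be
the same $\mu/k$, which is what the package uses.)

## Parameters

| parameter | units | default (docs/tests) | meaning |
|---|---|---|---|
| `mu` | 1/time | $\ln 2$ | growth rate; doubling time $\tau = \ln 2/\mu$ |
| `k` | 1/(size$^\lambda\cdot$time) | $\ln 2$ | splitting-rate constant |
| `s0` | size | 1 | initial (birth) size at $t=0$ |
| `lambda` | — | 1 | rate exponent; 1 gives the adder |

Parameters are carried in absolute units, but the dynamics depend only on
the dimensionless $\theta = k s_0^\lambda/\mu$ and on $\mu t$ (rescaling
$s_0 \to c s_0$, $k \to k/c$ leaves the counting process unchanged — a
property test in the suite). The canonical point $\mu = k = \ln 2$,
$s_0 = 1$ gives $\tau = 1$, $\theta = 1$, $\bar\Delta = 1$, so times read
in doubling times and sizes relative to $s_0$; all documentation and
default configurations use it.

## Three solution routes, cross-validated

**Quadrature recursion.** $P_0$ is available in closed form,
$P_0(t) = \exp[-\theta(e^{\mu t}-1)]$, and each subsequent state follows
from the one-sided variation-of-constants integral
$$P_i(t) = \frac{k s_0}{2^{i-1}}
  e^{-\frac{k s_0}{\mu 2^i} e^{\mu t}}
  \int_0^t e^{\mu t' + \frac{k s_0}{\mu 2^i} e^{\mu t'}} P_{i-1}(t')\,dt'.$$
`p_i_recursive()` evaluates the cumulative integral on an internally
refined uniform grid with a four-point Newton–Cotes rule ($O(h^4)$
globally), doubling the refinement until two successive evaluations agree
within `quad_tol` (default $10^{-9}$; refinement capped at 64× with a
diagnostic error beyond that). The exponentials are combined in log space
so the large intermediate factors $e^{\pm b e^{\mu t}}$ never overflow.

**Finite state projection.** `fsp_propagate()` integrates the master
equation truncated at state $N$ with `deSolve::ode` (lsoda, default
rtol/atol $10^{-9}/10^{-12}$ — probabilities near $10^{-6}$ must be
resolved). There is no reflecting boundary: probability flowing past $N$
accumulates as *leak* $1-\sum_i P_i$, reported per time and never
silently renormalized, so the leak at the final time bounds the
truncation error of the whole distribution. `fsp_auto_truncate()` finds
the smallest $N$ meeting a leak bound by doubling and then bisecting.
Small negative round-off values are kept in the raw matrix (conservation
checks need them) and clamped to zero only in derived reports.

**Matrix exponential.** With $x = e^{\mu t}$ the truncated system becomes
autonomous with a constant bidiagonal generator, so
$P(t) = \exp[A(e^{\mu t}-1)/\mu]P(0)$ exactly; `fsp_propagate_expm()`
(via `Matrix::expm`) is a third, independent cross-check of the ODE
route. The test suite requires the recursion and FSP to agree to
$10^{-5}$ for the first five states across $\theta \in \{0.5, 1, 2\}$,
and FSP to match the $P_0$ closed form to $10^{-6}$ over seven doubling
times.

**Stochastic simulation.** The cumulative hazard of one cycle is
analytic for every $\lambda > 0$, so `simulate_lineage()` samples
interdivision times by exact inverse transform —
$T = \frac{1}{\lambda\mu}\ln(1 + \lambda\mu E / (k s_b^\lambda))$ with
$E$ unit-exponential — rather than by thinning; event times are
continuous and the simulation is exact for the model. The sampler takes
$E$ as an argument so that all randomness is owned by the simulator:
ensembles use one L'Ecuyer-CMRG substream per cell
(`parallel::nextRNGStream`), making runs reproducible from the seed and
independent of iteration order.

## Statistics of ensembles: two numerical caveats

Two places where the obvious estimator misleads, and what the package
does instead:

**Window censoring of pooled cycles.** Pooling all cycles completed
within a fixed horizon oversamples fast cycles: the last, unfinished
cycle of each lineage — disproportionately a slow one with a large added
size — is discarded. At $\theta = 1$ this inflates the pooled
$CV^2_\Delta$ by about 5% and biases the adder regression intercept
visibly downward. Cycle statistics (in `cmd_validate()` and the tests)
therefore exclude cycles born within $3\tau$ of the horizon; the residual
censoring probability of an included cycle is
$\exp[-\theta(e^{3\mu\tau}-1)] \approx e^{-7}$, i.e. negligible.

**Coverage of confidence bands along a path.** The ensemble mean path
deviates from the exact FSP moments by a *correlated* error: a
$10^4$-cell ensemble that wanders one standard error high stays high for
times of order $\tau$. Pointwise, the normal-approximation 95% intervals
are well calibrated (checked against replicate ensembles during
development), but the *fraction of grid times* covered by a single
path's band is volatile — roughly five to ten effectively independent
stretches in 512 grid times. The concordance checks therefore average
the coverage fraction over three independent ensembles instead of
trusting one, leaving the band construction and the 90% threshold
unchanged. The variance bands use a variance-of-variance estimate and
are documented as approximate; they are mildly anti-conservative for the
strongly skewed size distribution.

## The synthetic ensembles and real data

`simulate_ensemble()` emulates a mother-machine experiment: a fixed
number of independent lineages, one descendant kept per division, all
started at a known size (or an initial-size distribution: fixed, uniform,
lognormal, or explicit atoms). It does **not** emulate partitioning
noise, growth-rate variability between cells or over time, multi-step
division machinery, or lineage trees in which both daughters proliferate.
Consequently, passing tests show that the analytic and numeric machinery
is internally consistent and exact for *this* model — not that real
added-size noise is exponential ($CV^2_\Delta \approx 0.1$ in published
measurements, far below the model's 1) nor that real populations lack
mother–daughter correlations introduced by partitioning errors.

## Size distribution, envelopes and mixtures

At any time the population size density is a weighted Dirac mixture
$\rho(s|t) = \sum_i \delta(s - s_0 e^{\mu t}/2^i) P_i(t)$
(`size_atoms()`); means and variances follow by direct summation
(`size_moments()`), and the tests require them to match the atom-set
moments to round-off. Asymptotically the distributions become invariant
under $(n, t) \to (n+1, t+\tau)$ (`periodicity_residual()` measures the
sup-norm residual, which the tests require to fall below $10^{-3}$ by the
eighth pulse at $\theta = 1$), so for large $t$ the atom pattern repeats
every doubling time.

Sweeping the initial size moves the atom loci continuously and traces an
enveloping curve; `envelope_atoms()` represents that envelope as the
tagged union of per-source atoms — any smoothing is a visualization
choice, never part of the data model. For a *distribution* of initial
sizes, `initial_size_mixture()` discretizes it into equal-probability
quantile nodes (deterministic, so tests are exact; the stochastic
cross-check uses sampled initial sizes in the simulator), solves each
node, and merges atoms that coincide in size to relative $10^{-9}$ —
e.g. a $2s_0$ component reproduces the $s_0$ component shifted by one
division index. Atoms lighter than $10^{-12}$ are dropped from output
tables only; conservation bookkeeping keeps them.

## Numerical choices and degenerate inputs

* Default output grid: 512 points on $[0, 7\tau]$, adjusted so the step
  divides $\tau$ exactly (the translation-invariance residual needs
  aligned grids; misaligned grids are a precondition error).
* `t = 0` inputs: the distribution is the point mass $\delta_{i,0}$, the
  atom set a single atom at $s_0$, moments $(0, 0)$ and $(s_0, 0)$;
  `fsp_auto_truncate(..., t_final = 0)` returns 1.
* A zero hazard draw ($E = 0$) divides immediately ($T = 0$); negative
  draws, nonpositive rates or sizes, and leak bounds outside $(0,1)$ are
  domain errors.
* Truncation: leak is an error *bound*, not a nuisance — moments over the
  truncated support carry a `leak_flag` when the deficit exceeds
  $10\times$ the ODE relative tolerance.

## Problem sizes used by the checks

The shipped test suite runs the full cross-validation at $\theta = 1$
(with $\theta \in \{0.5, 2\}$ for the recursion–FSP agreement): FSP to
$10\tau$ with auto-chosen truncation ($N \le 40$), three replicate
$10^4$-cell ensembles on 512 grid times for the concordance check,
$10^4$ pooled cycles for the added-size noise and adder regression, and
$4000$-cell ensembles for the per-source envelope and mixture
cross-checks. These sizes make every stochastic band scale like the
$10^4$-trajectory setting the model targets while keeping the default
run lightweight.

## Known limitations

* The closed-form survival, the quadrature recursion and the
  matrix-exponential route require $\lambda = 1$; for $\lambda \neq 1$
  the FSP ODE route and the exact sampler remain available.
* The long-time variance plateau of the division count is computed
  numerically (no closed expression is attempted).
* Confidence bands are asymptotic-normal approximations; for very small
  ensembles or very early times (few divided cells) they are crude.
* The envelope is a discrete atom union; it does not define a continuous
  limiting density.
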