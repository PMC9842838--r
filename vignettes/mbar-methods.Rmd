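---
title: "Free-energy estimation with mbar: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy estimation with mbar: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbar)
```

## The statistical model

Simulation post-processing starts from pooled samples of K thermodynamic
states. State $i$ is specified by its reduced potential
$u_i(x) = \beta_i [U_i(x) + p_i V(x) + \mu_i^T n(x)]$; omitted terms
(no barostat, no open ensemble) simply contribute zero. The multistate
Bennett acceptance ratio estimator treats the pooled data as draws from a
mixture of the K sampled distributions and solves

$$\hat f_i = -\ln \sum_{j=1}^{K}\sum_{n=1}^{N_j}
  \frac{\exp[-u_i(x_{jn})]}
       {\sum_{k=1}^{K} N_k \exp[\hat f_k - u_k(x_{jn})]}$$

for all dimensionless free energies simultaneously. Free energies are
defined only up to a constant; the package anchors $\hat f_1 = 0$. The
estimator assumes the samples are **uncorrelated** and that neighboring
states **overlap** in configuration space; neither assumption is checked by
the mathematics, so the package reports a per-state effective sample size
$\mathrm{ESS}_k = 1/\sum_n w_{kn}^2$ of the normalized reweighting weights
and warns below 50.

Unsampled target states are reached by appending them with $N = 0$: their
free energy, averages and PMFs are computed from the same cached
per-sample log-denominators. A PMF is the special case of an indicator
observable on a binned collective variable, reported in kT with the minimum
over non-empty bins shifted to zero (a flag converts to kcal/mol at a
declared temperature).

## The four input modes

*Restraint* (umbrella sampling): the shared system energy cancels between
numerator and denominator, so the matrix rows contain only the window
restraints $\beta k_i (z - z_i^{\mathrm{ref}})^2$. The restraint convention
is $k(\Delta z)^2$ with no $\tfrac12$; engines using $\tfrac12 k$ are
accommodated by `half_spring = TRUE`, which halves the constant on input.
Angular coordinates may declare a period, in which case displacements are
wrapped to the minimum image; the default is non-periodic.

*Scaling* (temperature replica exchange): rows are $\beta_i U_{system}$.
When a pressure is declared on a state the $pV$ term is included — also for
the reweighting target, since the target is defined by the same state
contract.

*Accumulation* (alchemical perturbation): only neighbor-state reduced
energies are used; each neighbor pair is solved as the two-state special
case (Bennett's method) and the differences are accumulated to the endpoint.
The coupling schedule itself is metadata; `+Inf` energies (core overlap at
decoupled endpoints) are legal and carry zero weight. A single inverse
temperature is assumed along a chain (isothermal transformation), matching
standard alchemical practice.

*Full potential energy* (solute tempering, dual-level QM/MM): rows are
$\beta_i[U_{\mathrm{col}(i)} + U_{restraint}^{(i)}]$ with explicitly named
energy columns; dual-level reweighting uses low-level columns plus window
restraints for the sampled states and the high-level column, unrestrained,
as the target.

## Numerical solution

Every sum is evaluated in log space (log-sum-exp), so no intermediate
exponential can overflow and infinite reduced potentials are handled
exactly. The solver runs plain self-consistent iteration until the max-norm
residual $\max_i |f_i - \mathrm{RHS}_i(f)|$ drops below $10^{-2}$, then
switches to damped Newton–Raphson on the $K-1$ free components, using the
gradient and Hessian of the convex objective whose stationary point is the
self-consistent equation. A Newton step is halved up to four times and
abandoned for a fixed-point step whenever it fails to reduce the residual,
so progress is monotone and the quadratic local rate is kept where it holds.
Defaults: tolerance $10^{-8}$, at most $10^5$ iterations; non-convergence
raises an error carrying the residual trace rather than returning a bad
fit. These are declared defaults of this implementation, not reconstructions
of any particular production code.

Two-state solves, used per neighbor pair in accumulation mode, reuse the
same machinery; the test suite checks them against an independent bisection
of the one-dimensional Bennett self-consistency equation, and the general
solver against a plain fixed-point iteration started from a different
point.

Units: energies enter in kcal/mol, temperatures in K, with
$k_B = 0.0019872041$ kcal/(mol·K); reduction to dimensionless form happens
exactly once, when the matrix is built.

## Uncertainty

Two resampling schemes are provided. *Block averaging* splits each state's
series into B contiguous-in-time blocks (default 10) and reports
$\mathrm{sd}(\mathrm{blocks})/\sqrt{B}$, which tolerates residual
autocorrelation. The *bootstrap* (default 50 replicates) resamples within
each state independently and assumes decorrelated input; a stride
subsampler is available for thinning, while autocorrelation-time estimation
is out of scope. All stochastic paths take explicit seeds.

Resampled PMF profiles need a gauge: each replicate is anchored by
subtracting its value at the full estimate's best-populated bin (the bin
most stable under resampling) before spreads are taken. The reported SE at
that anchor bin is therefore zero by construction — uncertainty on a PMF is
only ever defined relative to some reference point. For the same reason,
when a PMF is *compared* against ground truth in the tests, the two
profiles are aligned by the offset that minimizes the maximum absolute
deviation instead of comparing two independently min-shifted curves, which
would inject the noise of one arbitrary bin into every bin. The reported
PMF objects themselves always use the min-shift convention.

## The synthetic-data generators

The generators stand in for the MD demonstrations the estimator is normally
applied to, with ground truth built in: exact Gaussian draws from harmonic
states (closed-form free energies), umbrella windows and temperature
ladders on a double-well toy, linear-mixture alchemical chains, and
low-level/high-level umbrella data with a smooth energy correction. For the
1-D toys, samples are drawn *exactly* by inverse-CDF lookup on a fine grid,
matching the estimator's uncorrelated-samples premise; `mcmc_sample`
provides correlated Metropolis trajectories where a trajectory-like series
is wanted, with hard walls at the declared domain bounds so chain,
inverse-CDF sampler and quadrature references all target the same bounded
density. Every generator emits a manifest (parameters plus seed) sufficient
to regenerate its output bit-identically, and all reference values are
produced by quadrature or closed form at run time, never stored.

Study conditions were fixed once as realistic umbrella practice: a
double-well with 2.5 kcal/mol barrier and wells at ±1 on a [−1.35, 1.35]
domain, 21 windows at 0.1 spacing with k = 10 kcal/mol/Å² (window width
≈ 0.17, giving healthy neighbor overlap), 2000 samples per window at 300 K;
a four-temperature ladder 300–540 K for scaling mode; an 11-state linear
schedule between two equal-stiffness harmonic wells for accumulation mode; a
1 kT sinusoidal correction for the dual-level case. Accuracy grids use 25
bins on [−1.1, 1.1] (bin width comparable to the window spacing) for
comparisons against quadrature and 51 bins for the WHAM cross-check. What
passing these tests shows is that the estimator, solver and reweighting
machinery are correct at realistic problem sizes; what it cannot show is
robustness to the pathologies of real MD data — slow hidden degrees of
freedom, unconverged sampling, poorly overlapping states — which the ESS
diagnostics flag but cannot repair.

## WHAM reference

The binned WHAM implementation iterates the standard density-update /
window-normalization pair with the restraint evaluated at bin centers,
half-open bins (last closed), anchor on the first window and tolerance
$10^{-8}$. It exists as an internal cross-check — the binless estimator is
WHAM's zero-bin-width limit, and the tests verify the two converge toward
each other as bins shrink — not as a production path.

## Design choices on open points

- Zero-sample states are permitted only as appended targets; elsewhere they
  indicate an input error, since they contribute nothing to the mixture.
- General-sign observables use the direct weighted average rather than the
  logarithmic free-energy-ratio form, which requires a positive observable;
  the equivalence for positive observables is asserted in the tests.
- Multidimensional PMFs are supported for one and two collective variables;
  higher dimensions are rejected rather than silently binned.
- The total SE of an accumulation chain defaults to block averaging applied
  to the whole chain, because interior sample sets are shared by two pairs
  and summing per-pair variances would treat them as independent; the
  faster per-pair quadrature sum remains available with that caveat.
- Pipeline YAML uses `nbins` for the bin count: a bare `n` key is parsed as
  a boolean by YAML 1.1 readers.

## Limitations

The estimator inherits the limits of its inputs: no autocorrelation
correction beyond stride thinning, no analytic asymptotic covariance (only
resampling), no soft-core functional forms or engine log parsing (delimited
text is the interchange contract), and no stochastic solvers for very large
K. PMF accuracy claims hold on bins with effective counts above ~50;
sparser bins are reported but carry large errors, as the per-bin ESS makes
visible.
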