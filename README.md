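# mbar: multistate Bennett acceptance ratio estimation in R

Free-energy differences and thermodynamic averages from molecular-simulation
time series, for computational chemists and biophysicists who post-process
umbrella-sampling, replica-exchange, alchemical-perturbation or dual-level
QM/MM data.

## The estimator

Given samples from K thermodynamic states, each defined by a dimensionless
reduced potential

u_i(x) = β_i [ U_i(x) + p_i V(x) + μ_iᵀ n(x) ],

the multistate Bennett acceptance ratio (MBAR) estimator solves the
self-consistent equations

f̂_i = −ln Σ_{j,n} exp[−u_i(x_{jn})] / Σ_k N_k exp[f̂_k − u_k(x_{jn})]

for the dimensionless free energies f̂_i of all states simultaneously
(anchored at f̂₁ = 0, since only differences are defined). It is the
statistically optimal generalization of Bennett's two-state acceptance-ratio
method and the zero-bin-width limit of WHAM. Once solved, any unsampled
target state is reached by reweighting: its free energy, averages
⟨A⟩_target, and — with an indicator observable on a collective variable —
potentials of mean force (PMFs).

The package covers the four standard ways simulation data enter the
estimator:

| mode | typical source | what the matrix rows contain |
|---|---|---|
| restraint | umbrella sampling | β k_i (z − z_iʳᵉᶠ)² only (the shared system energy cancels) |
| scaling | temperature replica exchange | β_i U_system(x) |
| accumulation | alchemical FEP | neighbor-state reduced energies, chained two-state solves |
| full | solute tempering, dual-level QM/MM | β_i [U_column(x) + restraint] |

Uncertainties come from block averaging over time or within-state bootstrap;
a binned WHAM implementation is included as a cross-check, and synthetic-data
generators with closed-form or quadrature ground truth make every claim
testable.

## Worked example

Three harmonic (Gaussian) states with σ = 1, 1.5, 2 have analytic free
energies f_i = −ln(σ_i √2π), so Δf to state 1 is −ln(σ_i/σ₁):

```r
library(mbar)
g   <- gen_harmonic_states(sigma = c(1, 1.5, 2), n = 5000, seed = 1)
fit <- mbar(g$u)
summary(fit)
#> MBAR estimate (dimensionless free energies, f_1 = 0)
#>
#>  state    N     f_hat   delta_f     ess
#>      1 5000  0.000000  0.000000 12813.9
#>      2 5000 -0.408878 -0.408878 14812.7
#>      3 5000 -0.692334 -0.692334 12890.2
#>
#> Converged in 5 iterations; residual 4.54e-12 ( tolerance 1e-08 )
```

The estimates −0.4089 and −0.6923 recover the analytic −ln(1.5) = −0.4055
and −ln(2) = −0.6931 within the Monte-Carlo error of 15,000 samples; `ess`
is the effective sample size of the reweighting to each state.

An umbrella-sampling PMF on a double-well potential (21 windows from −1 to 1,
k = 10 kcal/mol/Å², 300 K), reweighted to the restraint-free target
(`u_target = 0`) with block-averaged errors:

```r
pot <- toy_potential("double_well", height = 2.5, width = 1,
                     bounds = c(-1.35, 1.35))
beta <- beta_from_temperature(300)
gen  <- gen_umbrella_windows(pot, window_ladder(-1, 1, 0.1), spring_k = 10,
                             beta = beta, n = 2000, seed = 1)
fit  <- mbar(build_reduced_matrix(gen$states, gen$samplesets))
pmf  <- mbar_pmf(fit, 0, gen$cv, seq(-1.1, 1.1, length.out = 26), se = "block")
pmf
#> <mbar_pmf> 25 bins, 25 occupied; units: kT
#>   range: 0 to 4.19 kT
```

The estimated barrier of 4.19 kT sits on the exact quadrature value 4.16 kT
for this potential. `as.data.frame(pmf)` gives per-bin values, standard
errors and effective counts; `plot(pmf)` draws the profile.

FEP chains are estimated from neighbor energies only
(`fep_estimate(sets)`; pairwise Bennett solves accumulated to the endpoint
difference), temperature ladders through `thermo_state("scaling", ...)`, and
dual-level reweighting through `"full"`-mode states naming the low-level
energy column plus a target state naming the high-level column.

A command-line driver (`inst/cli/mbar.R`) wraps the same functions behind
`umbrella | remd | fep | full | synth` subcommands with a YAML
configuration; CLI and library calls produce identical numbers.

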