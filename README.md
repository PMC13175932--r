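# rationalode

Identification of rational-form ordinary differential equations from
time-series data by null-space analysis of observational libraries.

## The problem

Biochemical networks — enzyme kinetics, gene regulation, metabolic
oscillators — are governed by ODEs whose right-hand sides are *rational*
functions,

    dx_k/dt = N(x) / D(x),

with polynomial numerator and denominator (Michaelis–Menten saturation,
Hill regulation, competitive degradation).  Plain sparse regression over a
polynomial feature library cannot represent these dynamics.  The implicit
rearrangement

    dx_k/dt * D(x) - N(x) = 0

is linear in the unknown coefficients: evaluating all monomials up to
degree *d* on the samples and pairing them with the same monomials times
the measured derivative gives the observational library

    B = [ Theta(X) , dx_k * Theta(X) ],   q = 2 * choose(n + d, d) columns,

and every rational model the data obey is a null vector of `B`.  The
package extracts sparse null vectors via the eigendecomposition of the
q×q observable matrix `B'B` (or the SVD of `B`), resolves the polynomial
degeneracy of clean-data null spaces by minimal-degree selection, chooses
model structure by scanning nested sub-libraries with held-out validation,
thresholds at a fixed λ = 1e-7, re-estimates coefficients on the selected
support, and reconstructs explicit rational equations with named kinetic
parameters.

It ships four classic benchmark generators — Michaelis–Menten uptake, the
*B. subtilis* competence circuit, penicillin production kinetics and the
seven-species yeast glycolysis oscillator — plus total-variation
regularised differentiation for noisy data, edge truncation, structural
(L0) and parametric (L2/Frobenius) error metrics, and a reproducible
noise-sweep protocol.  Intended users: researchers in systems biology and
data-driven dynamics who want a tested, deterministic reference
implementation of implicit null-space identification.

## Worked example

```r
library(rationalode)

spec <- benchmark_spec("mm")        # Michaelis-Menten study design
data <- simulate_benchmark(spec)    # 2 trajectories, t = 0..20 s, dt = 1 s
fit  <- rational_ode(data, state = "x", degree = 4)
fit
#> Rational ODE identified by null-space analysis
#>   equation: dx/dt = (0.18 + -0.9*x) / (0.3 + 1*x)
#>   support: 4 of 10 library terms (lambda = 1e-07, scan back end)
#>   accepted sub-library: degree <= 1 in (x), q = 4, held-out error 1.28e-10

recover_parameters(fit, "mm")
#>   jx Vmax   Km
#>  0.6  1.5  0.3
```

The identified equation is `(0.18 - 0.9 x)/(0.3 + x)` — algebraically
identical to `0.6 - 1.5 x / (0.3 + x)`, i.e. the input rate `jx = 0.6`,
maximal uptake `Vmax = 1.5` and Michaelis constant `Km = 0.3` used by the
simulator.  The 4-term support out of 10 library columns (`1, x, dx, x*dx`)
is the exact structure of the implicit form; the relative error of the
recovered parameters is about 1e-15.

The same pipeline at benchmark scale:

```r
bm <- run_benchmark("glycolysis")   # 450 trajectories, q = 3432 per equation
bm$report$structural_error          #> 0          (all 7 supports exact)
bm$report$frobenius_error           #> 7.737e-14  (26 named coefficients)
```

And under heavy measurement noise:

```r
sw <- noise_sweep(noise_sweep_config(sigma_levels = 0.1,
                                     n_initial_conditions = 400))
sw$structural_error                 #> 0   (exact 4-term support at sigma = 0.1)
```

A thin command-line front end is installed with the package
(`inst/cli/rationalode.R`):

```sh
Rscript inst/cli/rationalode.R run-benchmark mm --out results/mm --seed 1
Rscript inst/cli/rationalode.R noise-sweep --config sweep.yaml --out results/sweep
```

## Package layout

- `R/models.R` — benchmark systems, simulation, ground-truth implicit forms
- `R/derivatives.R` — exact / finite-difference / TVRegDiff policies, truncation
- `R/obslib.R`, `R/terms.R` — monomial enumeration and library construction
- `R/identify.R` — Gram reduction, null-vector extraction, sparsification
- `R/fit.R` — the `rational_ode()` front end and the sub-library scan
- `R/reconstruct.R` — explicit models, parameter recovery, re-simulation
- `R/metrics.R` — structural and parametric error metrics
- `R/experiments.R` — benchmark orchestration, noise sweep, reports
- `vignettes/rational-ode-identification.Rmd` — the methods document
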