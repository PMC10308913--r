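---
title: "From a stoichiometric network to a calibrated fermentation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a stoichiometric network to a calibrated fermentation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gem2dmm)
```

## The modelling problem

Anaerobic carbohydrate fermenters such as the rumen bacterium *Fibrobacter
succinogenes* S85 convert glucose, cellobiose and cellulose mainly into
succinate, acetate, formate and CO2, storing part of the carbon as
glycogen and assimilating ammonia as their sole nitrogen source. A
genome-derived stoichiometric network describes *what* the organism can
do; a batch-culture experiment measures *how fast* concentrations change.
`gem2dmm` connects the two: it reduces a stoichiometric network to a
handful of macroscopic reactions via elementary flux mode (EFM) analysis
and turns those into an ordinary-differential-equation model whose rate
constants are estimated from time-series data.

The chain of models is:

1. **Mass balance.** With metabolite concentrations split into
   intracellular `x_i` and extracellular `x_e` parts,
   `dx/dt = S r(x)`, where `S` stacks the intracellular (`Si`) and
   extracellular (`Se`) stoichiometric blocks.
2. **Intracellular steady state.** `Si r = 0`. The admissible
   non-negative flux vectors form a convex polyhedral cone whose extreme
   rays are the elementary flux modes: minimal pathways that can operate
   at steady state.
3. **Macroscopic reactions.** Each mode `e` maps to the net extracellular
   conversion `Se e`, normalized to one unit of carbon substrate.
4. **Kinetics.** Each retained macroscopic reaction `i` proceeds at a
   saturating rate: Monod kinetics `rho_i = mu_max_i * s/(K + s) * B` for
   soluble substrates, Contois kinetics
   `rho_i = mu_max_i * s/(Kc*B + s) * B` for particulate cellulose, where
   the half-saturation point scales with the biomass that must colonize
   the fibre surface. Biomass additionally decays with a first-order
   death term `kd * B`.

## Interpretation of the kinetic rate

The saturating rate could multiply either the substrate column or the
biomass column of the macroscopic stoichiometry. This package interprets
`rho_i` as the **substrate-consumption rate** of reaction `i`:
`ds/dt = -sum_i rho_i` and `dB/dt = sum_i f'_i rho_i - kd*B`, with `f'_i`
the biomass yield converted from g/mmol to C-mol/mol. The interpretation
is isolated in one internal function (`reaction_rates()`) so the
alternative (biomass-production rate) can be swapped by dividing by
`f'_i` there; all tests would re-run unchanged apart from rate scales.

## Units and fixed constants

| quantity | value | unit | why |
|---|---|---|---|
| biomass composition | C3.69 H6.76 O2.66 N0.25 S0.010 | — | measured elemental composition of *F. succinogenes* biomass |
| biomass mass per C-mol | 26.401 | g/mol_C | from the composition above; converts C-mol bookkeeping to grams |
| Monod constant `K` | 9e-3 | M | fixed, not estimated: Monod affinity constants are practically non-identifiable from sparse noisy batch data |
| death rate `kd` | 8.33e-4 | 1/h | fixed first-order decay |
| OD conversion `alpha` | 6.15e-4 | M/OD | default; estimated for soluble substrates when OD is observed |
| glucose / cellobiose / cellulose molar mass | 180.16 / 342.30 / 648.56 | g/mol | cellulose handled as a 4-anhydroglucose unit |
| glycogen / glucan chain length | 6 / 5 | glucose units | fixes the carbon balance of the storage pathway; the glucan polymerization reaction `5 glc-1-P -> 5 Pi + glucan` closes it exactly |
| atomic masses | C 12.011, H 1.008, O 15.999, N 14.007, S 32.06 | g/mol | one fixed table; reproduces the 26.401 g/mol_C figure to 0.2% |

Glycogen is carried in the ODE state in glucose-equivalents (six per
storage unit). CO2 is integrated as the cumulative net exchange with the
100% CO2 headspace and may be negative (net uptake); it still enters the
carbon balance with one carbon per mole. Protons, ATP, CoA, PPi and the
"salts" pseudo-species are bookkeeping artifacts of the network reduction:
they are reported as cumulative fluxes, never as concentrations, because
the medium is buffered and they do not feed back on the kinetics.

## Numerical choices

* **Linear programming.** Flux balance analysis, yield maxima and
  essentiality run on a dense two-phase primal simplex with Bland's
  anti-cycling rule (`solve_lp()`), written for networks of tens to a few
  hundred reactions. Statuses are reported honestly; degenerate alternate
  optima may return any optimal vertex, so all comparisons use objective
  values or yields, which are unique. Fluxes below 1e-9 are reported as 0.
* **EFM enumeration.** Iterative double description over the positive
  orthant with the combinatorial adjacency test, floating-point with a
  1e-9 zero tolerance; exact rational arithmetic is not offered — on the
  intended network sizes the tolerance is orders of magnitude below any
  stoichiometric coefficient. Futile two-cycles created by splitting
  reversible reactions are removed post hoc. Balance rows are processed
  fewest-nonzeros-first and ties break lexicographically, so output order
  is deterministic. A mode cap (default 5e6) aborts with a progress
  message rather than exhausting memory.
* **Network reduction.** Unprotected intracellular metabolites are
  eliminated by exact column operations along the support of supplied
  steady-state flux vectors (fewest-connected metabolite first, ties by
  id; pivot by largest coefficient). The operation provably preserves the
  net production rate of every remaining metabolite for each supplied
  vector, which is the defining contract — tested to 1e-6 relative.
* **Hull reduction.** 2-D convex hulls come from `grDevices::chull`
  (counter-clockwise, duplicates collapsed). The minimal enclosing polygon
  is found by enumerating hull-vertex triangles in increasing area and
  accepting the first that contains the reference points (observed yields
  when available, the hull centroid otherwise); ties prefer triangles with
  larger summed biomass yield — a documented heuristic favouring
  growth-capable modes. If no triangle encloses the data the full hull is
  kept with a warning.
* **Integration.** `deSolve::lsoda` at `rtol = 1e-8` (1e-6 inside the
  estimation loop), with concentrations clamped at zero inside the
  right-hand side and an error on excursions beyond -1e-9.
* **Estimation.** The cost is a weighted residual sum of squares — the
  Gaussian negative log-likelihood with per-variable variances estimated
  from replicate scatter. Profiling the variances out of the likelihood
  instead is degenerate here: a concentrated `log(RSS)` term rewards
  interpolating any single variable arbitrarily well while ignoring the
  rest, and the optimizer finds exactly that hole; replicate-based
  variance estimates keep the weights anchored to the measurement error.
  Added to the weighted RSS is a penalty `lambda` per macroscopic
  reaction whose `mu_max` exceeds 1e-4/h, which prunes superfluous modes.
  Optimization runs in log10 parameter space: candidate starts (a Latin
  hypercube over `mu_max` in [1e-4, 2]/h plus data-driven starts built
  from the observed product increments) are ranked by one cost evaluation,
  and the best are polished by Nelder-Mead followed by BFGS. For
  cellulose, where OD is not measured, the initial biomass joins the free
  parameters.

## What the synthetic-data generator emulates — and what it does not

`generate_experiment()` mimics triplicate Hungate-tube batch cultures on
3 g/L carbohydrate sampled at 0, 5, 9, 13, 17, 20 and 24 h: it simulates
the true model, samples it, and adds independent Gaussian noise with
standard deviation `noise_cv * |signal|` floored at a detection limit
(0.1 mM for sugars, acids and ammonia; 0.01 OD — fixed, documented
choices), clipping at zero. These defaults are the culture protocol every
statistical claim in the package refers to; the inoculum is OD 0.05 and
the medium carries a 30 mM ammonia pool so nitrogen never limits 3 g/L of
sugar.

The generator does **not** emulate: OD-biomass nonlinearity at high
densities, enzymatic assay chemistry, sampling-volume effects, pH or
product inhibition, gas-liquid CO2 transfer, or the glycogen futile cycle
(storage and degradation run simultaneously in the real organism; the
steady-state EFM formalism cannot represent that cycle, and neither can
any model built from it here). Passing the recovery tests therefore shows
that the estimation machinery is correct and well-posed under the stated
noise model — not that the model family captures every feature of real
cultures.

## Design choices where the design was open

* The nine packaged macroscopic reactions for glucose ship as data; the
  four-reaction reference model (e2, e5, e6, e9 with rate constants
  0.037, 0.031, 0.31, 0.004 /h) is the generating truth of all synthetic
  glucose experiments. Parameters for cellobiose and cellulose models are
  treated as unknowns to estimate, never invented.
* Per-substrate analyses close the other carbon sources by removing
  (zero-bounding) their uptake reactions rather than leaving them open;
  `max_yield()` honours closed reactions when it releases capacity bounds.
* Cellobiose counts as 2 and cellulose as 4 glucose equivalents
  throughout, so uptake-rate grids for those substrates span half and a
  quarter of the glucose range.
* Essentiality uses a 1% viability threshold by default.
* How per-pair hull triangles combine into one selected set is not
  canonical; the package unions them and de-duplicates modes that are
  equal as vectors (1e-9 per entry after unit-max normalization), and
  treats the resulting counts as behaviour to report, not to enforce.
* The packaged 63-reaction network is a synthetic stand-in constructed to
  mirror the printed structure of a reduced genome-derived model (36
  intracellular and 16 extracellular species, PPi-dependent glycolysis,
  the PEP-carboxykinase succinate route, pyruvate-formate lyase, a
  six-glucose glycogen cycle, a lumped biomass). It is carbon- and
  nitrogen-balanced by construction with water and charge implicit, so
  elemental checks on it are run for C (and N) only. Its redox coupling
  caps the acetate yield at 1 mol/mol glucose — a property of this
  stand-in, not of the organism's deposited network.

## Problem sizes used by the tests and the acceptance script

Exact elementary-mode checks run on the five toy networks (3-9 reactions)
against a brute-force support-enumeration oracle; hull code is checked
against an all-pairs half-plane oracle on 100-point clouds; ODE solutions
against a fixed-step RK4 integrator. The statistical recovery check runs
50 seeded synthetic glucose experiments (triplicates, 7 time points, 5%
noise) and requires all four rate constants within 15% of truth in at
least 90% of them; each fit polishes the two best-ranked starts. Full
enumeration of the multi-million-mode sets of a deposited reduced network
is cluster-scale and out of scope for the test suite; the cap and the
oracle equivalences are the desk-scale evidence that the enumerator is
exact.

## Known limitations

* The simplex solver is dense and unsuited to genome-scale (>5000
  reaction) networks; the reduction likewise.
* Monod `K` (and Contois `Kc`) are not estimated by default; freeing them
  on sparse data produces the classic parameter-correlation pathology,
  which `parameter_correlations()` diagnoses via a finite-difference
  Fisher information matrix.
* The dynamic model ignores glycogen futile cycling, pH and product
  inhibition; macroscopic stoichiometry printed to three decimals carries
  a ~1% carbon imbalance, so exact conservation tests use toy-derived
  (exactly closed) macro reactions.
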