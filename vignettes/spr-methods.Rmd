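---
title: "Models and methods for complex SPR sensorgram analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for complex SPR sensorgram analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprkin)
```

## Scope and rationale

`sprkin` analyses surface plasmon resonance (SPR) sensorgrams for weakly
binding, mechanistically complex analytes — the situation met when short,
intrinsically disordered peptides bind substrate-recognition domains. In
this regime affinities are tens of micromolar to millimolar, the highest
usable concentrations are solubility-limited, saturation is rarely
approached, and global fits with the standard 1:1 model show systematic
residuals. The package therefore treats *mechanism discrimination* and
*robust apparent-affinity ranking* as first-class outputs, alongside the
usual kinetic parameter estimation.

Because raw biosensor exports for such studies are typically not deposited,
the package includes a synthetic-experiment generator that emulates the
assay design and artifact structure, so that the entire chain — referencing,
fitting, diagnostics — is testable end-to-end against known ground truth.

## Binding schemes

All schemes are expressed as mass-action rate equations for the bound
species, with the measured response the sum of bound signals. Units are
molar and seconds internally; every user-facing concentration is micromolar
(µM), responses are resonance units (RU).

**1:1 Langmuir.** `dR/dt = ka·C·(Rmax − R) − kd·R`. During association at
constant `C` the closed form is `R(t) = Req·(1 − exp(−(ka·C + kd)·t))` with
`Req = Rmax·C/(C + KD)`, `KD = kd/ka`; dissociation is a single exponential
with rate `kd`. Dissociation is *memoryless*: traces from different contact
times, aligned at the end of injection and normalised, coincide.

**Two-state induced fit.** `A + B ⇌ AB ⇌ AB*` with binding rates
`ka1, kd1` and isomerisation rates `ka2, kd2` (both first-order). When
isomerisation is slow (`kd2 ≪ kd1`), longer injections accumulate the
locked state `AB*` and aligned dissociation slows with contact time — the
observable this scheme is tested by. The overall equilibrium constant is
`KD,app = KD1/(1 + ka2/kd2)`.

**Heterogeneous ligand.** Two independent site classes, each with its own
`ka, kd, Rmax` — the standard model of an immobilisation-heterogeneous
surface. Dissociation is bi-exponential with contact-time-independent rates.

**Fuzzy ensemble.** `n` binding modes (registers/orientations of a
disordered peptide on one site) competing for a single shared capacity:

```
dr_i/dt = ka_i·C·(Rmax − Σ_j r_j) − kd_i·r_i + Σ_j (k[j,i]·r_j − k[i,j]·r_i)
```

The interconversion matrix `k[i,j]` formalises rearrangement between bound
modes without dissociation. This is this package's explicit minimal
realisation of the verbal "heterogeneous ensemble of complexes" picture;
whether interconversion is fast, slow or absent is deliberately left as a
free regime for the user to explore, because contact-time invariance
constrains it (fast or absent redistribution) without identifying it.

## Numerical strategy

At piecewise-constant `C` all four schemes are *linear* in the bound-species
vector, `dr/dt = A·r + b`. The package exploits this three ways:

1. `simulate_mechanism()` integrates phase-by-phase with `deSolve::lsoda`
   (relative tolerance 1e-8 by default, analytic Jacobian `A`), the generic
   route that would also serve nonlinear extensions;
2. an internal exact propagator solves each phase by eigendecomposition of
   `A` (`r(t) = r_ss + V e^{Λt} V⁻¹ (r0 − r_ss)`), used as the fast path
   inside global fitting and cross-checked against route 1 in the tests to
   1e-6·Rmax on randomized instances;
3. `matexp_reference()` propagates the *free-sites ≈ Rmax* linearisation,
   valid only far from saturation; it refuses inputs whose predicted
   occupancy exceeds 1% of capacity and serves as a further independent
   oracle at low occupancy.

Steady-state responses come from the 1:1 closed form or the stationary
linear solve (`steady_state_response()`); with zero interconversion the
ensemble solution reduces to competitive binding
`Req = Rmax·Σx_i/(1 + Σx_i)`, `x_i = C/KD_i`, which the tests verify.

Phase boundaries are half-open `[start, end)`; grids are compared at 1e-9 s
tolerance to be robust to floating-point grid construction.

## The synthetic experiment

`experiment_design()` defaults mirror the emulated assay: twofold dilutions
from 200 µM down to 0.78 µM (nine concentrations; a 50 µM top gives seven),
60 s or 15 s injections, 15 s dissociation, 10 Hz sampling, ~9 kRU of a
36 kDa immobilised domain, and two zero-concentration blank cycles placed
first and last in each series. Binding capacity follows the stoichiometric
rule `Rmax = immobilisation·(analyte mass/ligand mass)·active fraction`
with a default active fraction of 0.25, a realistic value for an
amine-coupled surface.

`noise_model()` adds, per cycle: Gaussian noise (sd 0.15 RU), baseline
drift (uniform ±0.02 RU/s), injection-boundary pressure spikes (up to
20 RU within ±0.5 s of the boundaries), and a DMSO bulk mismatch (uniform
±0.1%, 8 RU per %). These magnitudes are plausible for a modern instrument
and are design parameters, not measurements; all are overridable and a
`noise_off()` model gives the pure mechanism signal. Two deliberate
interpretations:

* Drift is applied to the **active channel only** and, by default, drawn
  once per experiment. Drift common to both channels would vanish at
  reference subtraction, leaving blank referencing nothing to test; the
  implementation treats drift as the differential surface trend that
  double referencing exists to remove. Per-cycle independent drift is
  available via `drift_shared = FALSE`.
* The bulk offset appears in both channels, scaled by 0.95 in the active
  channel (excluded volume over the protein layer), so that a residual
  survives reference subtraction for solvent correction to remove — as on
  the real instrument.

Contact-time series (`generate_contact_time_series()`, defaults 15–140 s at
one concentration, constant 15 s dissociation) include one blank per
contact time, since every contact time has its own grid and double
referencing needs a grid-matched blank.

What the generator does **not** emulate: surface decay and regeneration
carry-over between cycles, needle-rinse effects, mass-transport limitation,
and surface-to-surface variability. Passing tests therefore demonstrate
correctness of the analysis chain under the stated artifact model, not
robustness to every pathology of real data.

Melt curves use the two-state van't Hoff model,
`f(T) = 1/(1 + exp((ΔH_vH/R)(1/T − 1/Tm)))` (temperatures in kelvin), with
linear folded/unfolded baselines; defaults Tm 69 °C, ΔH_vH 400 kJ/mol —
a typical mid-size folded domain — over a 35–95 °C scan at 0.25 °C steps.

## Preprocessing

The correction chain (`preprocess_set()`) is: reference subtraction →
spike masking → solvent correction → blank subtraction. Masking precedes
solvent correction because boundary spikes are pressure artifacts, not bulk
signal, and must not be pushed through the calibration. Applied to a
noiseless set the chain returns the pure mechanism signal to better than
1e-9 RU (verified). Masked points are excluded, never interpolated, and all
operations propagate masks by union.

Report points are the mean over the final 1 s of association with a 0.5 s
guard before the injection end. The guard keeps the window clear of the
masked spike region; the window mean is robust to noise. Replicate cycles
at the same concentration contribute separate report points — ranking
decisions should see cycle-to-cycle scatter, not a prematurely averaged
value.

## Fitting

`fit_steady_state()` fits `Req(C) = Rmax·C/(KD + C)` by bounded
Levenberg–Marquardt with `Rmax` floating. The fit is flagged *unreliable*
when the top concentration is below the KD estimate or KD runs into its
bound — the no-saturation regime in which an apparent KD is at best a
ranking statistic. Binding efficiency (`binding_efficiency()`) is the
zero-intercept least-squares slope over the lowest concentrations
(default 3); in the low-concentration limit it converges to `Rmax/KD` and
is the preferred ranking statistic when curvature is minimal. The
"initial slope" reading as a zero-intercept low-C regression is this
package's documented choice.

`fit_kinetic()` minimises the pooled squared residuals over all cycles with
kinetic parameters and capacity shared, on log10-scaled parameters with
bounds `ka ∈ [1e2, 1e9] M⁻¹s⁻¹`, first-order rates `∈ [1e-5, 10] s⁻¹`, and
`Rmax` within a decade of the stoichiometric cap. Weighting is uniform (no
error model is assumed). Optimisation is multi-started from a deterministic
3×3 logarithmic grid over the primary `(ka, kd)`; each start runs a short
exploratory Levenberg–Marquardt leg, the best (ties: lower RSS, then lower
`ka`) is refined to convergence. Standard errors come from the Gauss–Newton
Hessian via the delta method; bound hits are flagged.

Model comparison (`compare_models()`) uses the corrected Akaike criterion
`AICc = n·log(RSS/n) + 2k + 2k(k+1)/(n−k−1)` with `k` counting the noise
variance, plus a Wald–Wolfowitz runs test on the pooled residuals as a
systematic-misfit flag (z < −4). Two numerical-honesty rules:

* RSS values are floored at a relative 1e-8 of the data scale before
  ranking, so two fits that both reproduce noiseless data at machine
  precision compare as equal and parsimony decides.
* The *preferred* model applies the conventional decisive-evidence rule:
  a more complex scheme is preferred only when its criterion beats every
  simpler competitor by more than 10 units. On replicated 1:1-truth
  simulations, nested schemes win by chance margins of 2–3 units (they
  absorb noise), whereas a genuinely wrong mechanism loses by thousands;
  the margin of 10 separates these regimes cleanly. The spec-level
  "indistinguishable" declaration (top-two difference < 2) is reported
  independently of this rule.

## Diagnostics

`contact_time_invariance()` fits a single-exponential decay to each aligned
dissociation trace over a common window (default the first 10 s of the
15 s dissociation) and regresses log rate on contact time. The verdict is
*invariant* when the slope is equivalent to zero and the rate span is
below 10% of the mean. Equivalence, not point significance: the 95% CI is
compared against the band of slopes whose cumulative effect over the tested
contact-time range stays below the span tolerance. With eight precise rate
estimates, a point-null test flags sub-percent estimator biases as
"significant" even when all rates agree to 1%, which would contradict the
10% span tolerance; the equivalence band makes the two conditions coherent.

`detect_biphasic()` prefers a bi-exponential decay only when AICc improves
by more than 2 *and* both amplitudes exceed 3× the residual noise, and the
rates are separated by at least 1.5×.

`saturation_check()` reports the fraction of the fitted plateau reached at
the top concentration (saturated at ≥ 0.95) and a linearity flag: a
zero-intercept line is accepted when it matches the isotherm within an
AICc difference of 2 *after flooring both RSS at a 2% per-point relative
resolution*. Without the floor, exact noiseless data would always reject
the line regardless of curvature; the floor encodes "minimal curvature"
as deviations below a 2% measurement resolution.

`estimate_tm()` initialises at the extremum of the smoothed first
derivative (5-point centred moving average) and refines the full van't
Hoff model with linear baselines; it errors when the derivative shows no
transition above 6× its own noise. The estimate is equivariant under
affine signal scaling.

## Peptide mass convention

Average (not monoisotopic) residue masses at four decimals; water 18.0153;
acetylation +42.0367; C-terminal amidation −0.9847; lactam staple −18.0153
(one condensation water). Rounding is half-up to integer Da; the
full-precision value is always retained. Counter-ions (TFA salts) are
ignored. This convention reproduces seven of the nine tabulated
designed-analogue masses exactly (1779, 1493, 1222, 1451, 1449, 1488,
1014 Da); two rows (nominally 1403 and 1434 Da) differ by +2.4 and +0.7 Da
under any single consistent convention we examined, so the discrepancy is
documented rather than chased by adjusting constants. Staple formation
requires one amine-bearing (K) and one carboxyl-bearing (D/E) side chain;
incompatible pairs are rejected.

## Problem sizes and test design

The statistical acceptance suite runs: 100 randomized solver-equivalence
instances; 20 seeded replicates of the nine-concentration dilution design
for parameter recovery (median relative error and 95%-interval coverage);
20 replicates × 3 generating mechanisms for model discrimination;
20 replicates × 2 mechanisms for the contact-time discriminator; and
20 melt-curve replicates. These sizes give binomial resolution of ±~7% on
the ≥90% discrimination targets while keeping the default suite fast on a
single CPU. Kinetic ground truths in the test scenarios are scenario
parameters on the weak-binder scale (KD tens of µM; capacities from the
stoichiometric rule), chosen once and documented in the test helpers —
they are not measurements, and reproducing any published affinity value is
explicitly out of scope because the corresponding raw sensorgrams are not
public.

## Known limitations

* Mass transport, rebinding and surface decay are not modelled; on real
  data these can masquerade as mechanistic complexity.
* The fuzzy ensemble is a demonstration/simulation model; fitting its
  interconversion rates from single dilution series is generally
  ill-posed, and the package deliberately does not claim estimability.
* The heterogeneous-ligand fit orders sites only by the multi-start
  tie-break; label switching between equivalent optima is possible.
* Solvent correction assumes a piecewise-linear calibration spanning the
  observed bulk range; out-of-range bulk signals are clamped with a
  warning.
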