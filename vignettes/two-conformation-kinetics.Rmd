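---
title: "Two-conformation kinetics of CO binding to protoglobin: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-conformation kinetics of CO binding to protoglobin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

CO binding to *Methanosarcina acetivorans* protoglobin is biphasic in
both directions: two apparent association rates in stopped flow, two
dissociation rates under NO displacement, and two CO-concentration-
dependent bands in the lifetime distributions of flash-photolysis
rebinding. `pgbkinetics` models this with two tertiary conformations in
ligation-dependent equilibrium: a fast-rebinding, slowly dissociating
conformation `r` favoured when the haem is liganded, and a slow-rebinding,
rapidly dissociating conformation `t` favoured when it is not.

Each conformation has four states — bound (`B`), primary docking site
(`P`, the photoproduct with CO still in the distal pocket), secondary
docking site (`S`, a transient internal cavity) and unliganded (`U`) —
giving eight protein species plus the free CO pool `C`. The reactions
are strictly mass action:

* conformational exchange `B_r ⇌ B_t`, `P_r ⇌ P_t`, `U_r ⇌ U_t`
  (`k1/km1`, `k2/km2`, `k3/km3`; the un-prefixed rate is always r→t);
* geminate rebinding `P_c → B_c` (`kg_r`, `kg_t`) and thermal bond
  rupture `B_c → P_c` (`kdiss_r`, `kdiss_t`);
* docking-site migration `P_c ⇌ S_c` (`kmig_*`, `kret_*`);
* escape `P_c → U_c + CO` with a single shared `kout`, and bimolecular
  entry `U_c + CO → P_c` (`kin_r`, `kin_t`).

Three structural commitments deserve mention because the reaction graph
is not uniquely determined by the species list. First, solvent CO enters
*through the primary docking site* and thermal dissociation deposits CO
*into* it; this is what makes the closed forms
`k_ON = kin·kg/(kg+kout)` and `k_OFF = kdiss·kout/(kout+kg)` exact
branching-probability identities, and those closed forms in turn
reproduce the measured stopped-flow rates. Second, the secondary sites
neither exchange conformation nor connect to solvent — the minimal
reading consistent with their small, transient spectroscopic signature.
Third, `kout` is shared between conformations: the data do not resolve a
difference. Quaternary (dimer-level) cooperativity is deliberately
absent: the rebinding shape is independent of photolysis level, and CO
binding is independent of fractional saturation.

Detailed balance is *not* enforced. The published parameter set closes
the thermodynamic cycle `B_r → P_r → P_t → B_t → B_r` to only ≈ 0.46 of
`K1`; `equilibrium_summary()` reports this ratio as a diagnostic
(`cycle_closure`) rather than silently re-balancing rates that were
estimated kinetically.

## Experiment modes and observables

* **Flash photolysis** — the bound ensemble starts at the liganded
  equilibrium `f(B_r) = km1/(k1+km1)` (≈ 77/23 for the solution rates); a
  fraction `φ` is promoted to `P`, conformational identity preserved. The
  observable is the deoxy fraction normalized to the photolysed amount.
  With the published rates roughly a fifth of the photoproduct rebinds
  geminately within the first tens of nanoseconds, so the normalized
  signal at a 10 ns first sample is ≈ 0.8, not 1; normalization to the
  photolysed amount (not to the first sample) keeps traces at different
  temperatures comparable. An unphotolysed control (`φ = 0`) falls back
  to normalizing by total protein.
* **Stopped-flow association** — all protein unliganded at
  `f(U_t) = k3/(k3+km3)` (25 % / 75 %), CO at the post-mix concentration,
  mass-action CO depletion on by default (25 µM CO against 5–10 µM haem
  is not pseudo-first-order). Because the unliganded exchange
  (`~10^4–10^5 s^-1`) is much faster than binding at micromolar CO, the
  *simulated* association is nearly mono-exponential at the
  population-weighted rate — the model keeps the conformers in rapid
  pre-equilibrium on that time scale, while the real protein shows two
  resolved phases. The same applies to NO-displacement dissociation;
  see "Known limitations".
* **NO-displacement dissociation** — bound ensemble at the liganded
  equilibrium; NO scavenging of every escaped CO is represented by
  setting `kin_r = kin_t = 0` rather than by an explicit NO species,
  since NO capture is orders of magnitude faster than the seconds-scale
  observation and is never parameterized. The observable is the bound
  fraction.

Pseudo-first-order treatment of CO (constant `C`) is the default for
flash photolysis (CO ≥ 100 µM against 50 µM haem) and is switchable;
full mass action is the default for stopped flow.

## Numerical choices

**Integration.** `deSolve::lsoda` with an analytic Jacobian, `rtol =
1e-10` and `atol = 1e-13 ×` total protein. The system is stiff (rates
span `10^-2`–`10^8 s^-1` against a 10 ns–10 ms window); at these
tolerances total protein is conserved to better than `1e-9` relative and
the pseudo-first-order solution agrees with an eigen-decomposition of the
8×8 rate matrix to better than `1e-6`. Inside fitting objectives the
tolerance is relaxed to `1e-8` (residuals are noise-limited at `~10^-3`).

**Global fitting.** Free rate constants are optimized in `log10` space
(positivity by construction) with `minpack.lm` trust-region least
squares and finite-difference Jacobians, on the traces' own log-spaced
grids — the grid supplies per-decade weighting, so no extra weights are
applied beyond optional per-trace `1/σ`. The landscape is multi-modal
(notably a basin where `kin_t` and `kg_t` compensate while leaving
`k_ON,t` fixed), so `global_fit()` supports multi-start with log-uniform
±0.5-decade perturbations and an optional early stop once a start
reaches the noise floor. Parameters excluded from the free list are
returned bit-identical. Fitting a single CO concentration leaves
`kin_t` poorly constrained; adding a second concentration tightens it
several-fold, which is why two-pressure data are analysed jointly.
`kdiss_r/kdiss_t` are normally held fixed: rebinding traces are almost
insensitive to them, and they are better set through the closed-form
`k_OFF` relation from the measured dissociation rates.

**Multi-exponential fitting.** `y(t) = y0 + Σ A_i exp[−(t/τ_i)^{β_i}]`
with lifetimes in `log10` space; stretching exponents bounded to
`(0.2, 1]` to exclude the degenerate `β → 0` plateau. Without
user-supplied starting values a deterministic lattice of lifetime
placements (default 8) is tried and the best deviance kept. Components
are reported sorted by lifetime; exchangeable components that converge
onto the same lifetime are consolidated into one, leaving the duplicate
amplitude at zero.

**Maximum-entropy inversion.** The trace is modelled as
`y(t) = Σ_j g_j Δlogτ · exp(−t/τ_j) + baseline` on a uniform `log10 τ`
grid (default 25 points/decade over `10^-9`–`10^-1` s, covering the
measurement window with margin). `g ≥ 0` maximizes the Skilling entropy
relative to a flat prior, penalized by `χ²/2α`; the inner problem is
convex and solved by L-BFGS-B on `log g`, and `α` is tuned by bisection
on the classic criterion `χ² = N` (an L-curve would be a drop-in
replacement; the historic criterion is the default because it is what
the established MEM lifetime tools use). A constant basis element
absorbs non-decaying baselines. Near the target the `χ²(α)` curve is
very flat, so band positions are reproducible to the grid resolution
(0.04 decades) rather than to machine precision; reported areas are
stable to a few percent. Noise σ is taken from the trace metadata or
estimated from high-frequency late-time residuals.

**SVD of difference spectra.** Plain `svd()` with lag-1 autocorrelations
of the unit-norm spectral and temporal vectors; a component is
significant when both exceed 0.8 (common practice for time-resolved
spectra; configurable). Signs are fixed so each spectral vector's
dominant element is positive. No rotation of the significant subspace
toward "physical" spectra is attempted — raw components are interpreted
directly, and the second temporal component is compared post hoc with
the simulated slow-conformer occupancy rather than joined into the ODE
fit.

**Eyring analysis.** `ΔG‡ = RT ln(k_B T / h k)` with transmission
coefficient 1 and second-order rates on a 1 M standard state (the only
convention under which the bimolecular entry rates yield the tabulated
barriers). `fit_eyring()` is ordinary least squares of `ln(k h / k_B T)`
on `1/T` with slope/intercept covariance propagated to `ΔG‡(T)`.
Barriers are reported at 298.15 K by default: recomputing the tabulated
values shows most are reproduced at 298 K rather than at the nominal
293 K of the experiments (e.g. the fast geminate rate gives 6.89 at
298.15 K against a tabulated 6.9 ± 0.1, but 6.78 at 293.15 K), so the
reporting temperature is an explicit argument. One tabulated barrier
(`kdiss_r`, 19.6) is not reproduced at either temperature (19.3 at
298 K) and is treated as informational, not as a check.

## The synthetic-data generator

No raw traces are distributed with the analysis this package
re-implements, so every pipeline stage is exercised against synthetic
data generated from the scheme itself. The generator emulates:

* flash-photolysis traces on a 150-point log grid, 10 ns–10 ms, at 1 and
  0.1 atm CO (Henry's-law conversion, 1.03 mM/atm at 293 K, interpolated
  over 283–313 K from a config-overridable table — solubility values are
  instrument-book constants, not fitted quantities) and 10–40 °C via the
  Eyring machinery; additive i.i.d. Gaussian noise, σ = 2×10⁻³ of full
  amplitude by default, typical of averaged single-wavelength
  transients;
* stopped-flow traces with a 1 ms dead time (samples before it are
  discarded; no further instrument response is modelled), σ = 5×10⁻³;
  dissociation traces for amplitude work are shot-averaged (mean of 10
  replicates) because the two dissociation rates differ by only a factor
  2.5 and the experimental ±1 % amplitude estimates imply substantially
  averaged data;
* 70-delay time-resolved difference spectra as an outer product of two
  Gaussian-band component spectra (deoxy-minus-CO features near 436 and
  419 nm; band identities are cosmetic — every analysis acts on the
  matrix) with the model's own time courses: the deoxy fraction, and the
  normalized `U_t + P_t` occupancy as the structural-relaxation marker;
* the relaxation time course used for stretched-exponential recovery is
  generated at σ = 5×10⁻⁴: it stands for an SVD amplitude obtained from
  heavily shot-averaged spectra, and this noise level makes the
  synthetic fit's statistical error comparable to the two-significant-
  figure precision of the published lifetimes.

What the generator does *not* emulate: photoselection/anisotropy,
instrument response beyond dead-time truncation, drift or correlated
noise, and — by construction — any kinetics outside the scheme, in
particular genuinely stretched (time-extended) structural relaxation.
Passing recovery tests therefore demonstrates that the pipeline is
correct and well-conditioned under the stated conditions, not that the
scheme is the true generating process for laboratory data.

## Problem sizes

The shipped tests and the acceptance script use 150-point traces (80 for
self-fit checks), 70-delay spectra, 25–100 random rate sets for
integrator properties, 10-seed parameter-recovery ensembles with
3-start optimization, and 500-replicate Monte-Carlo calibration of the
Eyring errors — sizes chosen to match the information content of the
corresponding experiments while keeping a full run in minutes on one
core.

## Known limitations

* With the published rates, bound-state exchange (`~10^5 s^-1`)
  pre-equilibrates the conformers long before seconds-scale
  dissociation, so the *full scheme* predicts nearly mono-exponential
  NO-displacement kinetics, while the experiment resolves two phases.
  The analysis follows the source convention: dissociation quantities
  are computed through the closed-form `k_OFF` relation (and the
  measured 67/33 amplitude split when a synthetic dissociation trace is
  needed), and scheme simulations of dissociation are reported as-is.
  The same pre-equilibration makes simulated association
  mono-exponential. Resolving this tension — e.g. with slower liganded
  exchange — is model revision, not re-implementation, and is out of
  scope here.
* MEM inversions occasionally place a small spurious amplitude at
  lifetimes just below the data window when an unlucky noise draw makes
  the first samples look like a fast decay (an edge artifact shared by
  all regularized inversions); band reports should be read within the
  data window.
* The equilibrium constant `K1 = 0.3` predicted for the bound state is
  smaller than the 0.49 estimated from the measured dissociation
  amplitude ratio; the model reproduces both numbers in their own terms
  but does not reconcile them.
* Global-fit parameter recovery is guaranteed only for the identifiable
  subset (`kin_r`, `kg_r`, `k3`, `km3` with two CO concentrations); the
  `kin_t`/`kg_t` pair has a compensating degeneracy at realistic noise.
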