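---
title: "Models and methods: temperature dependence of enzyme turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: temperature dependence of enzyme turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermokin)
```

## The scientific problem

For many enzymes, plots of ln k against temperature are curved even far
from any unfolding transition. Macromolecular rate theory (MMRT)
attributes the curvature to a difference in heat capacity between the
enzyme–substrate ground state and the transition state, ΔC~P~^‡^. A
negative ΔC~P~^‡^ makes the activation enthalpy fall and the activation
entropy fall with temperature, producing a rate optimum that is purely a
property of the activation thermodynamics. Because ΔC~P~^‡^ reflects the
difference in the distribution of vibrational modes between the two
states, it is an experimental window on how global protein dynamics
couple to turnover — and comparing it across substrates that differ by a
single hydroxyl group "chemically maps" which active-site contacts
matter. This package implements the full analysis chain used in that
kind of study: transient and steady-state kinetics, MMRT fitting, KIE
temperature profiles, red edge excitation shift (REES) quantification,
and ensemble statistics from molecular simulations.

## Models

### MMRT

The central model is

$$\ln k = \ln\frac{\kappa k_B T}{h}
  - \frac{\Delta H^\ddagger_{T_0} + \Delta C_P^\ddagger (T - T_0)}{RT}
  + \frac{\Delta S^\ddagger_{T_0} + \Delta C_P^\ddagger \ln(T/T_0)}{R}$$

with rates in s^−1^, energies in kJ mol^−1^ (kJ mol^−1^ K^−1^ for
entropy and heat capacity), CODATA 2018 constants, transmission
coefficient κ = 1 by default, and T~0~ an arbitrary reference
temperature (default 348 K, the temperature at which the study system's
activation parameters are conventionally reported).

The key implementation observation is that
$y = \ln k - \ln(k_B T/h)$ is *linear* in the basis
$\{1, 1/T, \ln T\}$: with $y = a + b/T + c\ln T$,

* ΔC~P~^‡^ = R·c,
* ΔH^‡^(T₀) = R·(T₀·c − b),
* ΔS^‡^(T₀) = R·a + ΔC~P~^‡^·(1 + ln T₀).

`fit_mmrt()` therefore solves ordinary (optionally inverse-variance
weighted) linear least squares in closed form and maps the coefficients
— and, exactly, their covariance — back to the thermodynamic
parameters. This has three consequences the tests rely on: data
generated from the model are recovered to numerical precision; the fit
is *exactly* invariant to the choice of T₀ (ΔC~P~^‡^ and predicted
ln k(T) do not change; ΔH^‡^/ΔS^‡^ transform by their defining
identities); and with ΔC~P~^‡^ = 0 the model degenerates exactly to the
Eyring line in 1/T. Fitting is done in ln k space, unweighted by
default, because multiplicative rate noise is homoscedastic there.

Uncertainty is reported asymptotically from the linear solve and,
optionally, by residual-resampling bootstrap (`bootstrap_ci`), which is
deterministic given its seed. The published analysis reports ± errors
from a commercial fitting program whose method is unstated, so no
agreement check between the two error estimates is possible; both are
exposed.

KIE profiles (`fit_kie_pair`) fit the protiated and deuterated series
independently and form KIE(T) = exp(ln k~H~ − ln k~D~) on a grid.
ΔΔC~P~^‡^ is defined as ΔC~P~^‡^(D) − ΔC~P~^‡^(H); because the isotope
literature often quotes −ΔΔC~P~^‡^ as a positive number, the result
object carries both signs explicitly to avoid silent flips. Its SE
combines the two fit SEs in quadrature (the fits are independent).

### Transients

Stopped-flow traces are modelled as
`offset + Σ A_i exp(−(k_i t)^{b_i})` with one or two phases. The
stretch exponent b sits inside the power so that k keeps units of
s^−1^ for any b; b = 1 is a pure exponential, and values below 1
indicate a distribution of underlying rates. The alternative placement
exp(−k t^b^) was rejected because it gives k units that depend on b.
Fitting is Levenberg–Marquardt on top of a variable-projection-style
start: rate guesses are log-spaced across the observed time window
(8 per phase), and for each guess the amplitudes and offset — which
enter linearly — are solved by linear least squares before the full
nonlinear refinement. Phases are reported by decreasing amplitude
fraction (ties broken by descending rate), which makes "the major
phase" well defined. Model order (one vs two phases, stretch on/off,
substrate inhibition on/off) is always chosen by small-sample corrected
AIC, `AICc = n ln(RSS/n) + 2p + 2p(p+1)/(n−p−1)` with p counting the
mean-function parameters plus one for the error variance: an F-test
would only handle the nested comparisons.

### Steady-state kinetics

`fit_michaelis()` fits v = Vmax·S/(K~M~ + S) or, where high-substrate
inhibition is present, the uncompetitive single-K~i~ form
v = Vmax·S/(K~M~ + S + S²/K~i~), chosen because it is the standard
single-constant description of a nonproductive binding mode at high
substrate — consistent with the structural picture of an inactive
substrate orientation. That form has its rate maximum at
S\* = √(K~M~·K~i~), an identity the tests verify against grid search.
In `inhibition = "auto"` mode the inhibition term is retained only when
it wins on AICc *and* K~i~ is identifiable (below 10⁴·K~M~); otherwise
the plain hyperbola is returned. k~cat~ = Vmax/[E] uses whatever
enzyme (active-site) concentration the caller supplies — per-monomer
sites by default, since the tetramer-vs-monomer convention is a
reporting choice, not something the fit can decide.

### REES / QUBES

Each excitation row of an excitation–emission matrix is collapsed to
its center of spectral mass, CSM = Σf~i~λ~i~/Σf~i~, which is exactly
scale-invariant and bounded by the emission window. The CSM versus
excitation curve is summarised by CSM(λ~Ex~) = CSM₀ + A·exp(R·Δλ~Ex~).
Two conventions had to be fixed because the quantification literature
leaves them implicit: Δλ~Ex~ is referenced to the *minimum* excitation
wavelength in the curve (so A is the amplitude above CSM₀ at the bluest
excitation), and CSM₀ is fitted freely rather than pinned to the bluest
CSM. A/R (nm²) is the flexibility metric; reports label larger A/R as
"less rigid", which is the interpretive reading of the effect, not a
quantity the package asserts. Flat curves (SD below 10⁻⁶ nm) short-
circuit to A = 0 with R flagged unidentifiable instead of returning an
arbitrary degenerate exponential. An optional constant baseline,
estimated from the 10 reddest emission points, is off by default; no
Raman/scatter masking is applied beyond an emission-window restriction,
because no masking protocol is part of the method definition.

### Ensemble statistics

Superposition uses the Kabsch closed form (SVD with determinant
correction) — the named analysis tools do not document their algorithm,
but this is the standard choice and is cross-checked in the tests
against an independent implementation. RMSF and DCCM operate on
ensembles aligned to an iteratively refined average structure; the DCCM
uses the isotropic dot-product definition
C~ij~ = ⟨Δr~i~·Δr~j~⟩/√(⟨|Δr~i~|²⟩⟨|Δr~j~|²⟩), the convention of the
standard trajectory toolchain. Zero-variance atoms get zeroed
off-diagonal entries and an explicit flag rather than NaNs.

Substrate-orientation clustering aligns all frames on a shared fit
selection (active-site Cα atoms), computes pairwise substrate RMSD
*without* per-pair refitting — the point is orientation in the
active-site frame — and cuts an average-linkage dendrogram at the
epsilon distance (1.5 Å by default, the documented setting of the
source analysis). Per-pair best-fit RMSD is deliberately not offered.
Hydrogen bonds default to heavy-atom distance ≤ 3.0 Å and D–H···A
angle ≥ 135°, common toolchain defaults, and both cutoffs are
arguments because the method definition states none. Monomer averaging
of RMSF maps chains positionally onto one numbering and errors on
unequal chain lengths rather than truncating. Time windows (e.g.
"10–100 ns") are expressed as frame-range subsets by the caller; the
package never infers time units.

## Synthetic data: what it emulates and what it does not

All generators are seed-deterministic, with one seed stream per call
split per data point (or frame), so extending a grid never reshuffles
earlier draws; manifests record everything needed to regenerate the
output bit-identically. Rate noise is multiplicative log-normal, the
noise model under which the ln-space fits are correctly specified;
absorbance and intensity noise are additive Gaussian.

`gen_mmrt_series` takes ΔH^‡^, ΔC~P~^‡^ and an anchor point
(T, k) and solves ΔS^‡^ internally so the curve passes exactly through
the anchor. This matters: published activation-entropy values for the
study system are quoted in an unstated convention orders of magnitude
above typical values, so entropies are never used as generator inputs —
the intercept is pinned by the measured k~cat~ at 348 K instead.
`gen_eem` solves each row's Gaussian band center numerically so the
*discrete, truncated* CSM matches the QUBES target exactly at zero
noise (a truncated Gaussian's CSM is not its center). `gen_ensemble`
builds correlated displacements from a one-factor-per-axis block model
(within-block correlation ρ, signed across blocks), which is positive
semidefinite by construction, plus optional rigid-body motion and a
two-pose substrate mixture.

What passing tests on these data do show: the estimators recover the
parameters of correctly specified models at realistic noise, the
closed-form algebra is right, and the statistics match independent
brute-force implementations. What they do not show: robustness to
instrument dead time, detector shot noise, Raman scatter, real
photophysics, force-field accuracy, or non-exponential kinetics outside
the fitted model classes — none of which the generators emulate.

## Study conditions used by the recovery experiments

The recovery suite (tests and `scripts/acceptance.R`) parameterises the
generators from the published kinetic constants and checks that the
pipeline gets them back:

* MMRT: 14 temperatures spanning 293–358 K, 2% rate noise, 10 seeds;
  d-glucose (ΔH^‡^ 54.7 kJ/mol, ΔC~P~^‡^ −3.0 kJ/mol/K, k~cat~ 651.9
  min^−1^ at 348 K) and d-galactose (67.9, −1.1, 613.4).
* Michaelis–Menten: 10 concentrations spanning 0.1–20 mM at 3% noise
  (K~M~ 1.0 mM cases); 12 concentrations spanning 1–200 mM at 5% noise
  for the 4-deoxy substrate-inhibition case (K~M~ 15.04 mM, K~i~
  29.5 mM); 20 seeds each.
* Transients: 500 points over 0–15 s, two phases with 10×-separated
  rates (3 and 0.3 s^−1^), a 97/3 amplitude split over a 0.5 AU total
  amplitude, additive noise at 1% of the total amplitude, 10 seeds. The
  sampling rate and window are free choices (unstated in the source
  protocol), sized so both phases are resolved.
* KIE: a protiated/deuterated d-galactose pair with identical curvature
  and the deuterated anchor rate lower by the factor 1.7, 2% noise.
* Clustering: a 500-frame ensemble of 22 atoms (12 "active-site" fit
  atoms, 10 substrate atoms), two substrate poses 10 Å apart, dominant
  pose fraction 0.85 (the ">80%" case), 0.3 Å per-axis thermal noise,
  epsilon 1.5 Å.

These problem sizes keep the full test suite under half a minute on one
CPU while leaving comfortable statistical margins.

## Numerical choices and degenerate inputs

* Exponential and QUBES fits are multi-start (log-spaced rate grids, an
  R grid scaled to the excitation span) because these objectives have
  local minima; the linear subproblems (amplitudes, offsets, CSM₀) are
  always solved exactly at each start.
* Ties in model selection go to the simpler model; ties in phase
  ordering go to the faster phase.
* Cluster labels are 1-based, ordered by decreasing population, with
  medoid representatives; relabeling of permuted input is consistent by
  construction of the deterministic dendrogram cut.
* Degenerate inputs fail loudly and early: non-monotone time vectors,
  duplicate temperatures, nonpositive rates, ragged multi-model PDB
  files, empty selections, sub-minimum point counts, zero-variance
  bootstrap residuals (zero-width CIs with a warning), flat QUBES
  curves (flagged), zero-variance DCCM atoms (flagged).
* Unit handling is declared, never guessed: temperatures are converted
  from Celsius and rates from min^−1^ only when the caller says so;
  files written by the package carry their units in comment headers.

## Limitations

The MMRT fit assumes a single rate-limiting step with
temperature-independent ΔC~P~^‡^; two-state/unfolding models of
curvature are out of scope by design. The substrate-inhibition form is
the single-K~i~ uncompetitive one; more elaborate binding schemes are
not fitted. REES quantification is global (no per-tryptophan
decomposition), and the ensemble statistics assume imaged, whole
molecules (no periodic-boundary handling) with MD itself entirely out
of scope.
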