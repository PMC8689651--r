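# thermokin

Tools for dissecting how active-site substrate interactions govern the
temperature dependence of enzyme turnover. The package was built around
the study of a hyperthermophilic glucose dehydrogenase turning over a
panel of pyranose sugars (epimers and deoxy variants of D-glucose), where
the question is which individual enzyme–substrate hydrogen bonds control
the curvature of ln k versus T — but every component is generic.

It covers the full analysis chain:

* **Stopped-flow transient fitting** — sums of one or two exponentials
  with an optional stretch exponent,
  `offset + Σ A_i exp(−(k_i t)^{b_i})`, with AICc-based phase-count
  selection (`fit_transient`, `select_phase_count`).
* **Steady-state kinetics** — Michaelis–Menten fits with optional
  uncompetitive substrate inhibition,
  `v = Vmax·S / (K_M + S + S²/K_i)` (`fit_michaelis`,
  `build_temperature_series`).
* **Macromolecular rate theory (MMRT)** — fitting

  ```
  ln k = ln(κ k_B T / h) − [ΔH‡(T0) + ΔC_P‡ (T − T0)] / (R T)
                         + [ΔS‡(T0) + ΔC_P‡ ln(T/T0)] / R
  ```

  to temperature–rate series to extract the heat capacity of activation
  ΔC_P‡ (`fit_mmrt`), temperature-dependent activation thermodynamics
  (`thermo_profile`), rate optima (`mmrt_t_opt`), kinetic-isotope-effect
  profiles and ΔΔC_P‡ (`fit_kie_pair`), and residual-resampling bootstrap
  intervals (`bootstrap_ci`). The fit target `ln k − ln(k_B T/h)` is
  linear in {1, 1/T, ln T}, so the solve is closed-form and exactly
  invariant to the choice of reference temperature T0.
* **REES / QUBES spectroscopy** — center of spectral mass per excitation
  wavelength, `CSM = Σ f_i λ_i / Σ f_i` (`compute_csm`, `csm_curve`),
  and the QUBES exponential `CSM(λ_Ex) = CSM0 + A·exp(R·Δλ_Ex)` whose
  A/R ratio is a protein-flexibility metric (`fit_qubes`).
* **Ensemble (trajectory) statistics** — Kabsch superposition, iterative
  average structures, per-residue RMSF with monomer averaging and Welch
  tests between replicate sets, dynamical cross-correlation matrices,
  RMSD-based hierarchical clustering of substrate orientations
  (average linkage, epsilon cutoff), donor–acceptor distances and
  hydrogen-bond occupancies (`kabsch_superpose`, `average_structure`,
  `rmsf`, `rmsf_difference_test`, `dccm`, `cluster_orientations`,
  `donor_acceptor_distances`, `hbond_occupancy`), with multi-model PDB
  I/O (`read_multimodel_pdb`).
* **Synthetic data** — seed-deterministic generators for every input
  class (`gen_transient`, `gen_mm_series`, `gen_mmrt_series`, `gen_eem`,
  `gen_ensemble`), each attaching a manifest sufficient to regenerate
  its output bit-identically.
* **Pipeline** — a YAML/list config drives per-substrate kinetics →
  MMRT → KIE → REES and writes report tables (`run_pipeline`,
  `ddcp_table`).

## Worked example

Simulate a d-glucose-like temperature–rate series (ΔH‡ = 54.7 kJ/mol,
ΔC_P‡ = −3.0 kJ/mol/K, anchored to k_cat = 651.9 min⁻¹ at 348 K, 2%
rate noise) and refit it:

```r
library(thermokin)
ser <- gen_mmrt_series(dH_T0 = 54.7, dCp = -3.0, T0 = 348, anchor_T = 348,
                       anchor_k = 651.9 / 60, noise_sd = 0.02, seed = 101,
                       substrate = "d-glucose")
fit <- fit_mmrt(ser, T0 = 348)
fit
#> MMRT fit (n = 14, T0 = 348 K)
#>          dH_T0 (kJ/mol) dS_T0 (kJ/mol/K) dCp (kJ/mol/K)
#> estimate        53.5944          -0.0725        -3.0373
#> se               0.7917           0.0023         0.0304
#> residual RMS in ln k: 0.02075
mmrt_t_opt(fit$params)
#> [1] 366.6492
```

The fitted ΔC_P‡ of −3.04 ± 0.03 kJ mol⁻¹ K⁻¹ recovers the generating
−3.0; the negative heat capacity of activation makes ΔH‡ fall with
temperature and puts the rate optimum at ~367 K, below any unfolding
transition. A QUBES fit works the same way:

```r
q <- fit_qubes(csm_curve(gen_eem(csm0 = 353, A = 2, R = 0.2,
                                 noise_sd = 2, seed = 3)))
q
#>               csm0       A       R
#> estimate 353.15738 1.97555 0.20056
#> se         0.01373 0.00488 0.00014
#> A/R = 9.85 +/- 0.031 nm^2 (larger A/R is reported as less rigid)
```

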