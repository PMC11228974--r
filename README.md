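# ciufold

Collision-induced unfolding (CIU) analysis for traveling-wave ion
mobility-mass spectrometry (TWIMS), with companion gas-phase structure
tools: projection-approximation collision cross sections (CCS) and
Coulomb-minimized proton placement.

## Who this is for

Native mass spectrometrists studying protein-ligand stabilization: a
protein ion is quadrupole-selected, collisionally activated over a ramp of
trap voltages, and its arrival-time distribution (ATD) recorded at each
voltage. Unfolding shows up as a shift of the ATD toward longer drift
times; bound cofactors or drugs shift the unfolding transition to higher
energy. `ciufold` turns the raw per-voltage ATD matrices into calibrated
CCS fingerprints and quantitative stability statistics, and provides the
modelling-side counterparts needed to compare experiment with structure.

## What it computes

- **CCS calibration.** The corrected power-law TWIMS protocol:
  EDC-corrected drift times `td' = td − c·√(m/z)/1000`, charge- and
  reduced-mass-corrected literature CCS `Ω' = Ω·√μ/z`, and an OLS fit of
  `ln Ω' = ln A + X·ln td'`. The exponent `X` is the empirically derived
  calibration constant (≈1.4 on Synapt-class instruments).
- **CIU fingerprints and unfolding curves.** Column-max-normalised
  CCS-vs-voltage heatmaps, centroid-CCS traces, and ΔCCS curves relative
  to the unactivated protein.
- **CIU₅₀ / CIU_χ.** Four-parameter logistic fits
  `CCS(V) = L + (U−L)/(1+exp(−h(V−V₅₀)))` per replicate; `CIU_χ =
  V₅₀ − ln(100/χ − 1)/h` is the voltage inducing χ% of maximal unfolding.
  Replicate-aggregated profiles (mean ± sd) and one-way ANOVA across
  species. When a ligand is ejected at voltages inside the unfolding
  transition, CIU₅₀ can mask stabilization that low-χ statistics resolve —
  the package models this coupling explicitly.
- **Ligand ejection.** Logistic fits of ejected fraction vs voltage, and
  `Elab = z·V` conversion to laboratory-frame collision energy.
- **Charge placement.** Stochastic assignment of protons to chargeable
  sites (Asp, Glu, Lys, Arg, His, termini) minimizing unscreened Coulomb
  energy at a fixed net charge, with an exhaustive enumeration oracle for
  small systems.
- **Projection-approximation CCS.** Orientation-averaged Monte Carlo
  union-of-disks projection with a 1.4 Å probe, scaled by the empirical
  1.14 factor to `CCS_CALC`; plus Kabsch RMSD and center-of-mass distances
  for multi-model PDB trajectories.
- **Synthetic data.** A generator emulating the full experiment (three
  co-isolated species — apo, cofactor-bound, antibiotic-ternary — with a
  single unfolding event, quintuplicate replicates, a 20–60 V ramp refined
  at 42–44 V, and a voltage-dependent ejection channel) with stored ground
  truth, so the whole pipeline is testable offline.

## Worked example

```r
library(ciufold)

inst <- instrument_params(noise_sd = 0.03, n_replicates = 5)
ds   <- simulate_dataset(eftu_species_defaults(), inst, seed = 42)

model <- fit_calibration(
  simulate_calibrants(inst$cal_A, inst$cal_X, noise_sd = 0.002, seed = 42))
model
#> TWIMS power-law calibration: A = 0.803792, X = 1.40663
#>   EDC coefficient 1.57, drift gas mass 28.0134 Da
#>   fitted on 9 calibrants, R^2 = 0.999821

fits <- fit_dataset_species(ds, "ternary")
fits[[1]]
#> 4PL fit: L = 35.6, U = 39.1, CIU50 = 44.17 V, h = 0.9581 1/V (rss 0.00611, converged)

head(as.data.frame(chi_profile(fits)), 3)
#>   chi   mean_v      sd_v n
#> 1  10 41.47084 0.8494856 5
#> 2  20 42.31730 0.8648233 5
#> 3  30 42.87991 0.8750533 5

anova_compare(list(
  apo     = sapply(fit_dataset_species(ds, "apo"),    ciu_chi, chi = 10),
  binary  = sapply(fit_dataset_species(ds, "binary"), ciu_chi, chi = 10),
  ternary = sapply(fits, ciu_chi, chi = 10)), chi = 10)
#> one-way ANOVA at chi = 10%: F(2, 12) = 20.5, p = 0.0001349
```

Reading the output: the calibration recovers the generative power law
(A = 0.8, X = 1.41) from the noisy synthetic calibrant table; the ternary
complex's first replicate unfolds from 35.6 to 39.1 nm² with a midpoint
near 44 V; the χ-profile gives the replicate mean ± sd voltage for 10–90%
unfolding; and at χ = 10 the three species' stabilities separate clearly
(p ≈ 1e−4). `elab(43.8, 12)` converts a midpoint voltage to 525.6 eV for
the 12+ ion.

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/exec/ciufold`): `simulate`, `calibrate`, `fingerprint`, `fit`,
`chi`, `compare`, `eject`, `chargeplace`, `paccs`, `trajprofile`.

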