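---
title: "Models and methods behind ciufold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ciufold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ciufold` analyses collision-induced unfolding (CIU) experiments on native
protein ions and provides the gas-phase structure computations needed to
interpret them. This vignette documents the models, their assumptions, the
tunable parameters, and the design decisions taken where the methodology
left genuine choices.

## The two-state unfolding model

A quadrupole-selected protein ion activated in a trap cell populates, over
a collision-voltage ramp, two conformer families: a compact state of cross
section $\Omega_c$ and an extended state $\Omega_e$. The extended fraction
follows a logistic in voltage,

$$f(V) = \frac{1}{1 + e^{-h\,(V - V_{50})}},$$

so the centroid CCS of the arrival-time distribution (ATD) is exactly a
four-parameter logistic (4PL) with asymptotes $L = \Omega_c$,
$U = \Omega_e$, midpoint $V_{50}$ (the CIU$_{50}$) and steepness $h$
(1/V). The generalised statistic CIU$_\chi$ inverts the fitted curve:

$$V_\chi = V_{50} - \frac{1}{h}\ln\!\left(\frac{100}{\chi} - 1\right).$$

Assumptions: a *single* unfolding event (no multi-step segmentation), a
symmetric logistic in voltage (not log-voltage — the ramp axis is linear
and published CIU sigmoids are symmetric on it), and discrete conformer
families (bimodal ATDs) rather than a continuously drifting peak. These
match the fingerprint topology the common CIU tools assume.

## Ligand ejection and the masking effect

A ligand bound to the ternary complex is ejected with voltage; its
survival fraction is $S(V) = 1 - \mathrm{logistic}(V; V_{50}^{ej},
h_{ej})$. While bound, the ligand stabilises the compact fold, which we
model phenomenologically as a shift of the effective unfolding midpoint:

$$V_{50}^{\mathrm{eff}}(V) = V_{50}^{\mathrm{base}} + \Delta V_{lig}\,S(V).$$

As the ligand is lost, the stabilisation fades and the ternary species
converges to the binary baseline. The consequence — reproduced by the
synthetic generator and verified in the acceptance suite — is that
CIU$_{50}$ *underestimates* ligand stabilisation when ejection occurs at
voltages inside the unfolding transition, while low-$\chi$ statistics
(CIU$_{10}$–CIU$_{40}$) retain discrimination. No quantitative coupling
model is established in the literature; the linear-in-$S$ shift is this
package's choice, the simplest form with the right two limits.

Default coupling parameters: $V_{50}^{ej} = 42$ V (the reported
50%-ejection voltage for the antibiotic ternary system that motivated this
package), $h_{ej} = 0.5$ V$^{-1}$ and $\Delta V_{lig} = 2.0$ V, chosen
once so that with a 43.2 V binary baseline the ternary *apparent*
CIU$_{50}$ lands near the experimentally reported 43.8 V (the fitted
noise-free value is 43.80 V). A shallower ejection slope than unfolding
slope is required for any midpoint shift to survive at all; with a sharp
ejection step the ligand would be gone before the transition.

## TWIMS CCS calibration

Traveling-wave drift times need empirical calibration. The corrected
power-law protocol is implemented exactly:

1. $t_d' = t_d - c\,\sqrt{m/z}/1000$ (EDC flight-time correction;
   default $c = 1.57$, a typical first-generation Synapt value —
   configurable, since instruments differ),
2. $\Omega' = \Omega_{lit}\sqrt{\mu}/z$ with reduced mass
   $\mu = mM/(m+M)$ against the drift gas (N$_2$, 28.0134 Da by default),
3. ordinary least squares on $(\ln t_d', \ln \Omega')$: the slope is the
   empirical exponent $X$ (≈1.41 here), the intercept $\ln A$.

Fitting is unweighted in log-log space, matching the standard protocol's
linearization; no nonlinear refit is attempted. The model inverts in
closed form, which the generator uses to place ATD peaks at prescribed
CCS.

**Identifiability caveat.** Protein calibrants — native or denatured —
cluster in corrected CCS per charge (roughly 1.8–2.9 nm²·charge$^{-1}$),
so a realistic analyte-bracketing table gives the exponent little
leverage: 1% multiplicative drift-time noise propagates to
$\mathrm{sd}(X) \approx 0.03{-}0.10$ depending on the charge states
chosen. The shipped fixture (`calibrants_synthetic.csv`, literature-scale
stand-in values, not measured ones) is such a bracketing table and is fine
for *applying* a calibration; to *characterise the estimator* the test
suite uses `native_calibrant_ladder()`, nine native-like species from 6 to
800 kDa (CCS $\propto m^{2/3}$) spanning the full drift window, with which
$\mathrm{sd}(X) = 0.017$ under 1% noise.

## What the synthetic generator emulates — and what it does not

Emulated, with defaults forming a fixed "stated world": three co-isolated
12+ species of a ~43 kDa three-domain G-protein (apo 33.8→37.3 nm²,
$V_{50}$ 40.3 V; binary 34.7→38.2 nm², 43.2 V; ternary 35.6→39.1 nm²,
43.2 V base + ejection coupling), a 20–60 V ramp in 1 V steps refined to
0.5 V over 42–44 V (43 voltages), quintuplicate replicates, Gaussian
conformer peaks (σ = 0.15 ms) on a 0–14 ms pusher window binned at 0.1 ms,
3% multiplicative bin noise, and per-replicate unfolding-midpoint offsets
with sd 0.8/0.5/1.0 V (apo/binary/ternary) — the replicate sds reported
for the motivating experiment. Compact CCS, midpoints and replicate sds
are experimental-scale inputs; peak widths and noise levels are fixtures
(no instrument values exist for them), chosen to look like a well-tuned
Synapt ATD.

Not emulated: m/z spectra, charge-state or adduct envelopes, detector
saturation, ATD tailing, multi-step unfolding, and — importantly —
any $\chi$-dependent replicate error structure. The midpoint-offset noise
model shifts *every* CIU$_\chi$ of a replicate by the same amount, so
low-$\chi$ and CIU$_{50}$ group comparisons are almost perfectly
correlated across replicates. A green parameter-recovery test therefore
establishes estimator correctness, not that the generator reproduces the
full error anatomy of a real instrument; in particular the
"significant at low $\chi$ but not at $\chi = 50$" pattern becomes a
partly seed-dependent event under this noise model (see the acceptance
suite, criterion 4b) even though the underlying separations (1.05 V at
$\chi = 10$ vs 0.60 V at $\chi = 50$, noise-free) always order correctly.

## Numerical choices

- **4PL fitting**: Nelder-Mead (reltol $10^{-14}$) followed by BFGS
  polish, on $(L, U, V_{50}, \log h)$ so $h > 0$ by construction.
  Initialisation: $L = \min$, $U = \max$, $V_{50}$ at the interpolated
  half-range crossing, $h = 4/(\text{20–80\% span})$. A y-range below
  `min_amplitude` ($10^{-8}$) is flagged degenerate rather than fitted;
  non-convergence sets a flag and diagnostics, never an exception.
  Noise-free parameter recovery is better than 0.1% relative; a uniform
  voltage shift moves $V_{50}$ exactly.
- **ANOVA degeneracy**: zero within-group variance with equal means
  returns $p = 1$ with a flag (no test is possible); with unequal means,
  $F = \infty$, $p = 0$.
- **Proton placement**: greedy stochastic search with charge-conserving
  moves (proton swaps within a site class, paired acidic/basic toggles),
  restart-from-incumbent reseeding, 8 independent random restarts;
  termination when a full round of 250 proposals brings no improvement.
  Acidic sites carry −1 when unprotonated (carboxylate convention), basic
  +1 when protonated; energy is unscreened Coulomb in e²/Å, since only the
  ordering of configurations matters. Ties break to the lexicographically
  lowest state vector, making results reproducible; the exhaustive oracle
  (capped at $2^{20}$ configurations) uses the same tie-break. No
  intrinsic proton-affinity terms are included — pure Coulomb, flagged as
  a known simplification.
- **Representative site atoms**: Asp CG, Glu CD, Lys NZ, Arg CZ, His NE2,
  N/C-terminal backbone N/C; configurable, with fallback to the residue's
  last atom when the named atom is absent.
- **PA CCS**: uniform random orientations by the quaternion method; per
  orientation, Monte Carlo points uniform in the projected disks' bounding
  box; both streams seeded, so results are exactly reproducible.
  Internal units Å², reported in nm² (1 nm² = 100 Å²). The probe radius
  is 1.4 Å (standard gas-collision value) and the empirical correction is
  exactly ×1.14, applied only to computed PA values, never to experimental
  CCS. Standard error is computed over orientations and decreases as
  $1/\sqrt{n_{orient}}$.
- **Kabsch RMSD**: SVD superposition with the determinant sign correction;
  collinear selections are rejected (the rotation is under-determined).
  The test suite validates against an independent quaternion
  (Horn-method) implementation to $10^{-9}$.
- **Sub-seeding**: every (species, replicate, voltage) noise stream gets
  `(base + 1000003 i + 7919 j + 104729 k) mod (2^31 − 1)`, keeping seeds
  valid 32-bit integers while decorrelating streams; regeneration from the
  same master seed is bit-identical.

## Open choices documented

- **Elab**: laboratory-frame energy is $z \times V$ (12+ at 30–60 V gives
  360–720 eV). A published abstract-level statement pairing 40–50 V with
  "480–500 eV" is inconsistent with that definition at the upper end; the
  package uses $z\,V$ throughout and does not attempt to reconcile it.
- **ΔCCS vs absolute CCS for fitting**: identical for a symmetric 4PL (a
  constant y-shift changes $L, U$ but not $V_{50}$ or $h$); fits are run
  on whichever curve is supplied, and `delta_ccs()` is a presentation
  transform with the reference at the lowest (unactivated) voltage.
- **Per-replicate fitting**: CIU$_\chi$ statistics are computed per
  replicate and aggregated (mean ± sd), matching the quintuplicate
  mean-and-sd reporting convention; fitting a pooled mean curve is
  possible but not the default, as it discards replicate variance needed
  for ANOVA.
- **Multiple testing**: per-$\chi$ ANOVAs are reported without correction
  across the $\chi$ grid, mirroring field practice; users comparing many
  $\chi$ values should apply their own correction.

## Known limitations

Single-transition curves only; no drift-time smoothing beyond what the
binning implies; no trajectory-method or scattering CCS (projection
approximation systematically underestimates for concave surfaces, which
is exactly what the 1.14 factor compensates on average); no pKa weighting
in charge placement; PDB parsing is deliberately minimal (fixed columns,
first model or all models, altloc A). The CLI covers the pipeline but not
vendor raw files — input is the plain CSV ATD-matrix dialect.
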