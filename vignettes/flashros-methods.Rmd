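---
title: "Radiolysis ROS kinetics under FLASH and PBS delivery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiolysis ROS kinetics under FLASH and PBS delivery: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flashros)
```

## The model

`flashros` simulates the homogeneous chemistry that follows energy
deposition in tissue-like water: each integrated species $M_i$ obeys

$$\frac{d[M_i]}{dt} \;=\; G_i\,\rho_w\,\dot D(t)\;+\;\sum_j S_{ij}\,r_j,$$

where $G_i$ is the primary radiolytic yield (µmol/J), $\rho_w$ the water
density (kg/L), $\dot D(t)$ the instantaneous dose rate (Gy/s), and the
$r_j$ are mass-action reaction rates with stoichiometry $S$. The source
term creates the five primary water-radiolysis products (hydrated
electrons, OH· and H· radicals, H₂ and H₂O₂) in proportion to the dose
rate; everything downstream — oxygen chemistry, superoxide, glutathione
scavenging, alkyl/alkyl-peroxyl lipid chemistry and the alkyl
hydroperoxide (ROOH) endpoint — follows from the reaction table shipped
as plain text in `inst/extdata/reactions.tsv`.

The core state comprises the twelve radiolysis/peroxidation species plus
dissolved oxygen (integrated as a consumable by default; `ros_species(o2_dynamic
= FALSE)` pins it) and a set of tracked inert sinks (O⁻·, O₃⁻, the RH⁻
and RH₂· adducts, the R–R dimer and the ROH/RO termination products).
Water (55.3 M), the generic organic substrate RH (1 M), the oxidisable
lipid pool LH, H⁺/OH⁻ at pH 7 and Fe²⁺ (default 0) are constant pools
folded into pseudo-first-order constants at build time.

ROOH is the damage surrogate: it integrates the peroxyl-radical (ROO·)
population through two first-order channels — H-abstraction from the
lipid substrate (propagation, which also regenerates a carbon-centred
radical) and H-donation by the antioxidant pool (termination of the
radical, production of the hydroperoxide). The dose-rate (FLASH)
dependence of the endpoint arises from the competition between those
first-order conversions and the bimolecular Russell termination
2 ROO· → O₂ + ROH + RO, which destroys peroxyl radicals *without* making
ROOH. At conventional dose rates the ROO· population stays dilute and
essentially all of it converts; when the same dose arrives within the
ROO· lifetime the quadratic channel removes an appreciable fraction, so
fast delivery produces measurably less ROOH. Transient oxygen depletion
reinforces the effect at high doses by starving the R· → ROO· oxygen
addition.

### Calibrated lipid-phase constants

Aqueous-phase rate constants in the table are standard radiolysis values.
Two lipid-phase constants are not well constrained by tabulated kinetics
and were calibrated once, then frozen:

* the **effective first-order ROO· → ROOH conversion**, default
  0.1092 s⁻¹, which together with the propagation channel
  (20 M⁻¹s⁻¹ × [LH] = 2.04 mM ⇒ 0.0408 s⁻¹) gives a total first-order
  peroxyl turnover of 0.15 s⁻¹ (≈ 6.7 s lifetime);
* the **peroxyl–peroxyl termination**, default event-rate constant
  2 × 10⁴ M⁻¹s⁻¹ (ROO· loss constant 4 × 10⁴ M⁻¹s⁻¹).

They were fitted jointly to the scattered-beam hydroperoxide yields of
the murine skin irradiation conditions (30 and 45 Gy at conventional
~1 Gy/s and FLASH ~100 Gy/s; reproduced to 2.7 % rms) — analogous to the
way the PBS charge calibration constant is fixed from one measured
delivery time (below). The resulting lifetime is also what the
multi-beam behaviour requires: sparing decays with the inter-beam
interval on a ~10 s scale and plateaus beyond ~60 s, which a sub-second
peroxyl lifetime cannot produce. Literature mass-action models of the
FLASH effect (Labarbe-type peroxyl-recombination kinetics) use the same
structure.

Sensitivity (measured on the constant-rate anchors): halving the total
first-order constant (0.15 → 0.07 s⁻¹) lowers the 30 Gy conventional
yield by ~16 % while moving the 8 Gy yields by only ~2 %; doubling the
termination constant at fixed lifetime lowers the 30 Gy conventional
yield by ~8 % and deepens the 30 Gy CONV–FLASH sparing by ~45 %. The
two constants are therefore separately identified by the four
scattered-beam anchors. With literal table values (`roo_decay`
0.65 s⁻¹ with no ROOH product, termination event 10⁴ M⁻¹s⁻¹,
[LH] = 1 M) the absolute yields are similar but dose-rate sparing
nearly vanishes, which contradicts every comparative observation the
model is meant to reproduce; the reconstruction is discussed further
under *Known limitations*.

Open switches: the anomalous first-order H₂O₂ disproportionation row is
included as tabulated (`build_network(h2o2_disprop = FALSE)` disables it;
it shifts ROOH by ≲ 1 % by recycling peroxide oxygen), the lipid radical
L· re-enters the alkyl pool by default (`lh_routing = "sink"` traps it
instead; ~3 % effect at 8 Gy), and a `termination_rooh_frac` branching
lets a fraction of Russell termination events score as ROOH (default 0).

### Tissue conditions

Skin is modelled as slightly hypoxic with 10 µM dissolved O₂ and 410 µM
glutathione (`skin_conditions()`). The aerated, scavenger-free
lipid-micelle conditions of the pulsed-electron validation use
0.21 atm × 1.3 mM/atm ≈ 273 µM O₂ via Henry's law at 25 °C and zero GSH
(`aerated_conditions()`). Primary yields are beam-quality specific
(`primary_yields("electron")` for 6 MeV electrons,
`primary_yields("proton")` for the 227 MeV entrance plateau).

## Dose delivery models

A **dose-rate waveform** is an ordered set of constant-rate segments with
implicit zero-rate gaps. Constructors cover constant-rate scattered
fields, pulsed electron trains (`floor(total/DPP)` full pulses plus one
trimmed pulse so the delivered dose is exact to 10⁻⁹ Gy; per-segment
rates are recomputed from the realised segment lengths to keep the sum
exact in floating point), and concatenated multi-beam schedules.

The **PBS field** is a square raster of Gaussian spots (σ = 2.38 mm at
the 8 mm shoot-through plateau; contributions beyond 5σ dropped,
< 4 × 10⁻⁶ of the peak). Spots sit at integer multiples of the spacing,
centred on the field, `2 floor(L/2s) + 1` per axis, scanned
serpentine-row-by-row from the bottom-left corner. All spots share one
MU weight; the weight is normalised so the mean voxel dose over the
analysis region equals the nominal dose. The analysis region is the
in-field area covered by the scan pattern (for 3 mm spacing in a 100 mm
field the outermost 2 mm strip has no spots above it and is excluded;
for 5 mm spacing the pattern reaches the field edge and the region is
the full square), one 3 mm layer of 1 × 1 mm lateral voxels.

Spot dwell time is `dwell = κ·Φ/I`: charge per spot is proportional to
its weight and beam-on time is charge over current. The calibration
constant κ is fixed **once** from a single measured delivery — the
40 × 40 mm, 5 mm, 8 Gy field at 500 nA takes 222.4 ms in total with
80 × 1 ms spot transitions — and every other delivery time is a
prediction. With this κ the model predicts 1211 ms for the 100 × 100 mm
5 mm field and 1781 ms for the 3 mm field (≈ +1.4 % and +1.2 % against
the measured 1194.4/1760.3 ms; the residual is the non-Gaussian halo of
the clinical dose kernel, which makes measured spot weights
field-size-dependent in a way a single lateral Gaussian cannot).

Each voxel sees its own waveform — rate `d_ij/dwell` while spot *j* is
on, zero during transitions — and its chemistry is integrated
independently (`simulate_field()`), by default on a centred-strata
subsample of the voxel grid (regional means from a 1-in-4 sample differ
from a 1-in-2 sample by well under 0.5 %: the maps are smooth).

## Metrics

`adr()` (voxel dose over field time), `dadr()` (dose-weighted mean of
instantaneous spot rates), and `pbsdr()` (98 % of the dose over the time
between the 1 % and 99 % cumulative-dose crossings, linearly
interpolated inside constant-rate segments) implement the standard PBS
dose-rate definitions. `rvh()` builds the ROS-volume histogram
(survival curve over equal-volume voxels); `rooh_at_volume(x, v)` is the
DVH-style ROOH[v%] statistic (v = 50: the volume median), and
`delta_rooh()` reports conventional-minus-UHDR sparing as a positive
number. `dose_response()` interpolates mean ROOH versus dose with a
monotone Hyman-filtered cubic spline (the functional form of the
dose–response fit is not otherwise constrained), and
`iso_rooh_equivalent()` inverts it for the iso-ROOH conventional dose
and the FLASH dose-modifying factor.

## Numerical choices

* Stiff integration uses deSolve's `vode` (BDF, internally generated
  full Jacobian) on a compiled C right-hand side, **restarting at every
  waveform discontinuity**; `lsode` and `radau` serve as automatic
  per-segment fallbacks because each code occasionally stalls on a
  different pathological segment. Defaults: `rtol` 10⁻⁶, `atol`
  10⁻¹³ M; tightening `rtol` tenfold moves the endpoint by < 0.1 %.
* First-order rate terms are evaluated linearly through zero while
  bimolecular factors are clamped at zero: tiny negative solver
  excursions then decay smoothly instead of exciting the kink of a
  clamped fast decay. Concentrations below −10³·atol abort the solve;
  smaller excursions are clamped at segment boundaries.
* The integration runs to 150 s after the final beam-off (the system is
  at equilibrium well before that; the peroxyl lifetime is ~7 s).
* An independent fixed-step backward-Euler integrator (step 10⁻⁸ s,
  chord-Newton with LU reuse, in C) cross-checks the adaptive solution
  on a 10 ms pulse to < 10⁻⁴ relative error per species.
* The verification suite runs field chemistry on sub-sampled voxel
  grids (strides 2–8 depending on the field; 100–600 ODE solves per
  field), which keeps each full field under ~1 minute while leaving
  regional means and medians stable to well under 1 %.

## What the synthetic scenarios do and do not show

All inputs are generated in code: there are no external data sets. The
scenario registry reproduces the study conditions (pulsed-electron
sweep at 40 Gy total; 8 Gy fields of 40–100 mm at 1–500 nA; 30 Gy
multi-beam schedules with 2-minute intervals). Passing tests therefore
demonstrate internal consistency of chemistry + delivery + metrics under
the idealised geometry — a flat equal-MU Gaussian field on a homogeneous
voxel grid — not agreement with measured dose maps: a clinical
treatment-planning kernel carries a nuclear halo and delivery noise that
produce in-field dose texture (several percent) that this model
deliberately omits.

## Known limitations

* **Absolute ROOH level.** After calibrating the lipid constants to the
  30/45 Gy scattered anchors, the predicted uniform 8 Gy, 100 Gy/s
  yield is 1.31 µM against the published 1.377 µM (−4.7 %); the
  relative dose, current, field-size and interval behaviour all
  reproduce, but the absolute 8 Gy level sits low. No single tabulated
  constant can be moved to close this gap without breaking either the
  higher-dose anchors or the sparing magnitudes; we report the model's
  own value rather than adjust two constants against the same target.
* **Threshold fractions are quasi-binary.** Because the equal-MU
  Gaussian field is flat to ~0.5 % inside the region, the fraction of
  voxels below a fixed ROOH threshold jumps from ≈ all to ≈ none as the
  plateau crosses the threshold; reproducing intermediate published
  fractions (e.g. ~80 %) requires the few-percent in-field dose
  heterogeneity of a clinical kernel.
* Homogeneous voxel chemistry (no intra-track heterogeneity, no
  diffusion), no oxygen resupply by perfusion, no pH dynamics, no
  Bragg-peak/range modelling, and no biology downstream of ROOH.
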