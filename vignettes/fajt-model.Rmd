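---
title: "The flat-absorbing jaw-tracking collimator model"
author: "fajtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The flat-absorbing jaw-tracking collimator model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fajtrace)
```

## The problem

Monte Carlo dose calculation for radiotherapy plans is dominated by the
treatment head: most particles leaving the target are absorbed in the
secondary collimators (the jaws) and never reach the patient, yet a full
simulation spends most of its time transporting them. `fajtrace`
implements a fast secondary-collimator model for this bottleneck. Each jaw
pair is replaced by a single perfectly absorbing plane at the *top*
(target-side) surface of the pair: a particle whose ray strikes the plane
inside the projected opening continues in vacuum; any other particle is
terminated. Transmission through and scatter off the jaws are deliberately
neglected. The model supports jaw tracking — jaws moving in tandem with
the MLC during IMRT and VMAT delivery — by sampling a fractional monitor
unit (MU) per particle and interpolating both the jaw edges and the MLC
leaf positions at that MU, which keeps the two collimation stages
synchronized.

The top surface, rather than the jaw midpoint or bottom, is the right
place for the absorbing plane because it rejects both diverging and
downward-aimed particles most effectively; a parallel beam makes the
distinction obvious, since the projected opening of a divergent field
scales with the plane height. A regression test holds this against a
mid-jaw variant.

## Phase-space recycling with azimuthal redistribution

The incident phase space (PhspA, scored above the jaws) is held in RAM and
read cyclically from a uniformly random start record, so parallel runs
with different seeds consume independent stretches. Each source particle
is recycled `n_recycle` times (default 20) and every copy is rotated by an
independent uniform azimuth about the beam axis — azimuthal particle
redistribution (APR). APR preserves radius, polar angle, energy and weight
exactly while decorrelating the copies laterally, suppressing the latent
variance that re-using a finite phase space would otherwise imprint.
Records whose radius exceeds the projected aperture diagonal (plus a 10%
margin) are discarded at read time and counted, not stored, so one store
serves any field up to that size.

The collimated store (PhspB, scored below the MLC) is produced with an
*exact-count* contract: the loop runs until PhspB holds exactly
`n_requested` particles, and the number of source records consumed,
`n_read`, is determined on the fly from the rejection rate. Keeping
`|PhspB| = n_requested` means the downstream dose engine never restarts or
truncates a phase space.

Two independent RNG streams (azimuth angles, MU draws), derived from one
master seed, make runs bit-reproducible; enabling or disabling the MU
stream cannot perturb the azimuth sequence. The MU is drawn per APR copy,
not per source particle: the original articulation leaves this open, and
copy-level draws maximize aperture decorrelation.

## Normalization

Dose is reported per *history-equivalent*:

```
n_hist_equiv = n_read * n_recycle * (source histories / source size)
```

Radius-rejected records count toward `n_read` because they represent
source histories that were examined and absorbed; each APR copy counts as
`1 / n_recycle` of a history. This keeps "dose per initial history"
semantics stable under recycling and rejection, which the test suite pins
with a doubling invariant (doubling `n_requested` leaves normalized dose
unchanged within statistics) and an exact partition identity (splitting a
particle set into quarters and pooling the quarter doses by their history
counts reproduces the single-run grid bit-for-bit).

## The MLC stage

The MLC is a first-order stand-in behind a stable module boundary:
a projected aperture at a single plane, located per particle by the
cross-leaf coordinate, with a bulk transmission factor applied to
under-leaf particles and a leaf-tip offset widening each opening.
Tongue-and-groove, interleaf leakage and in-leaf scatter are out of scope;
a richer leaf model can replace this stage without touching the jaw model.
With transmission 0 the MLC reduces to a second absorbing aperture.

Because both collimation stages are perfect absorbers, out-of-field dose
is systematically *underestimated* — the model's known accuracy trade-off.
The fluence outside the projected aperture is exactly zero (when MLC
transmission is 0) instead of the percent-level leakage of a real head.

## The synthetic source

The validated machine phase space such a model would normally consume is
proprietary, so the package ships a parameterized stand-in: photons from a
Gaussian focal spot (sigma 0.05 cm, about 1.2 mm FWHM — typical for a
modern C-arm linac), directions uniform in solid angle within a 0.25 rad
cone (wide enough to cover a 30 × 30 cm² field corner at isocenter with
margin), energies from a 10-bin 6 MV-like bremsstrahlung fixture peaking
near 0.5–2 MeV, scored at z = 20 cm above the first jaw plane at 28 cm.
These values are declared fixtures chosen once for plausibility; they are
not fits to any machine's beam data. The synthetic source has no electron
contamination, no off-axis softening and no flattening-filter shape, so
passing tests demonstrate the collimation and bookkeeping machinery, not
agreement with a clinical beam.

## The kerma dose engine

The phantom-side engine is deliberately kerma-level, standing in for a
full condensed-history code at desk scale. Particles are ray-traced
through the voxel grid with the exact incremental grid-crossing walk; the
energy deposited in a voxel segment is the closed-form kerma integral
`w E (mu_en/mu) (exp(-tau_in) - exp(-tau_out))` with water attenuation
tables interpolated log-log. There is no secondary-electron transport, no
buildup and no scatter dose: depth-dose curves therefore peak at the
surface rather than at dmax. Charged particles deposit their energy in
their entry voxel. Per-voxel variance is accumulated history by history,
with all APR copies of one source delivery sharing a history so that their
correlation is counted.

Statistical run sizing follows the usual uncertainty-targeting procedure:
a pilot run's median relative sigma over voxels above 10% of the maximum
dose is scaled by the inverse-square-root law
(`estimate_required_histories()`) to reach the 1% target before a
production run.

## Absolute dose and monitor backscatter

Relative dose converts to Gy through the calibration chain
`D' = Do · TMR(dref, 10×10) · Dcal / DMC(dref, 10×10) · MU · Sb`, with
calibration in SAD conditions (10 × 10 cm² field, SSD 90 cm, dref =
10 cm). `Sb` corrects for radiation backscattered from the jaws into the
monitor chamber — an effect a scatter-free jaw model cannot simulate, so
it comes from a lookup table indexed by jaw opening. The shipped table is
a smooth synthetic surface within ~1% of unity, normalized to
Sb(10,10) = 1; measured tables drop in as CSV. For dynamic fields one Sb
is computed per control-point segment (at the segment-midpoint aperture,
consistent with linear-in-MU interpolation; a node mode is available) and
averaged with MU weights; VMAT arcs are split into per-segment sub-fields,
each converted with its own Sb. The TMR entry at (dref, 10×10) is treated
as a fixed calibration constant — the fixture table stores 0.739 there.

## Dose comparison

The evaluation stack is the standard trio: 3D gamma (dose difference in
percent of the global reference maximum combined with
distance-to-agreement), the signed gradient-weighted chi index
`chi = (D_eval - D_ref) / sqrt((tol·Dmax)² + dta²|∇D_ref|²)`, and RMSD in
percent of maximum, all restricted to voxels above a dose threshold
(default 10% of maximum), with optional isodose-band reporting. Gamma and
chi are both reported because gamma is biased upward by statistical noise.
Two numerical choices matter:

* Global percent-of-maximum normalization by default; local
  normalization sits behind a flag.
* The gamma search visits voxel centers only — no sub-voxel
  interpolation. The search is radius-limited by the point where the
  distance term alone exceeds the running best, which is provably exact:
  the test suite checks it against an exhaustive brute-force
  minimization to 1e-9 on random smooth grids. The price is a
  conservative bias on grids coarser than the DTA.

The chi definition is the standard gradient-weighted dose difference; the
closed form for a shifted linear ramp,
`chi = shift·slope / sqrt(tol² + dta²·slope²)`, is pinned in the tests.

## The analytic open-field reference

End-to-end accuracy is judged against an in-repo closed-form reference:
for a point-like source, an ideal absorbing aperture and a kerma-level
water phantom, the expected dose at a voxel is the in-cone fluence
`1/(Ω r²)` times the aperture coverage of the voxel footprint, attenuated
along the water path, summed over spectrum bins. The focal spot enters in
closed form too: a source point offset by `x0` shifts the projected edge
at depth `z` by `x0 (1 - z/z_top)`, so the edge indicator is convolved
with a Gaussian of width `sigma |z/z_top - 1|` before the footprint
integration. This reference integrates the same physics the simulation
samples, but directly — no phase space, no ray-trace, no voxel walk — so
agreement (gamma 2%/2 mm pass rates above 99% above the 10% isodose at
SSD 90) exercises the entire pipeline: source, APR, absorbing jaws,
projection arithmetic, deposition and normalization.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use a 2–8 × 10⁶-particle
synthetic source; open-field runs score 10⁶ particles for fluence-edge
checks and size the dose runs by the 1% uncertainty target (about 10⁷
scored particles for 10 × 10 on the 82³ × 5 mm phantom, capped at 3 × 10⁷
for 30 × 30). These sizes were chosen as the package's desk-scale
validation conditions. Every stochastic stage records its seed in the run
manifest; identical seeds reproduce stores, reports and dose grids
bit-for-bit.

## Known limitations

* No jaw transmission or scatter; out-of-field dose is underestimated by
  construction.
* The MLC stage is a single-plane bulk-transmission model.
* The kerma engine has no electron transport: no buildup region, no
  penumbra blurring from secondary electrons, and heterogeneity handling
  by radiological path only.
* The synthetic source is a fixture, not a beam model; absolute agreement
  with measured data is out of scope.
* Gamma uses voxel-center search only; on 5 mm grids with 2 mm DTA it
  effectively reduces to the dose-difference test.
* Couch rotations and dynamic collimator rotation are unsupported; DICOM
  RT Plan import is stubbed (the JSON plan dialect is the interface).
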