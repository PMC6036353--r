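# fajtrace

Fast secondary-collimator modeling for linac Monte Carlo dose
verification, in R.

Most of the cost of a treatment-head Monte Carlo simulation goes into
particles that the secondary collimators (jaws) absorb. `fajtrace`
implements the flat-absorbing jaw-tracking model of that bottleneck: each
jaw pair becomes a single perfectly absorbing plane at the pair's top
(target-side) surface. A particle read from the incident phase space
(PhspA) is recycled with azimuthal particle redistribution (APR),
ray-traced in vacuum to each jaw plane, terminated if it strikes inside
the jaw material's projection, passed through a single-plane MLC stage,
and scored to a collimated phase space (PhspB) of exactly the requested
size. For IMRT/VMAT with jaw tracking, every recycled copy samples a
fractional monitor unit that fixes jaw edges *and* MLC leaves together:

```
D' = Do · TMR(dref, 10×10) · Dcal(dmax, 10×10) / DMC(dref, 10×10) · MU · Sb
```

converts the resulting relative dose `Do` (Gy per initial history) to Gy,
with `Sb` the monitor-backscatter factor looked up from the jaw opening
(MU-weighted over control points for IMRT, per sub-field for VMAT arcs).

The package is aimed at medical-physics tooling work: it bundles
IAEA-dialect phase-space I/O, a synthetic 6 MV-like photon source (the
stand-in for proprietary machine phase spaces), a JSON treatment-plan
dialect with control-point interpolation and VMAT/IMRT splitting, a
kerma-level voxel dose engine (Rcpp), absolute-dose calibration, and the
3D gamma / chi / RMSD comparison stack with isodose-band reports.

## Worked example: an open 10 × 10 cm² field

```r
library(fajtrace)

model  <- source_model(seed = 1)              # synthetic PhspA source
phspA  <- generate_phspA(model, 5e5)
geom   <- collimator_geometry()               # Y jaws at 28 cm, X at 36 cm
jaws   <- c(-5, 5, -5, 5)                     # 10 x 10 at isocenter

reader <- cyclic_reader(phspA, seed = 2,
                        r_max = default_r_max(jaws, attr(phspA, "z_plane")))
cfg    <- collimation_config(n_requested = 2e5, n_recycle = 20, seed = 3)
run    <- collimate_static(reader, geom, cfg, list(jaws = jaws))
run$report
#> FAJT collimation report
#>   source particles read (n_read): 195230
#>   APR copies examined:            375654
#>     rejected upward (w <= 0):     0
#>     absorbed by jaws:             175654
#>     absorbed by MLC:              0
#>     scored to PhspB:              200000
#>   reader wrapped: FALSE
```

PhspB holds exactly the 200 000 particles requested; `n_read` was found
on the fly from the rejection rate. Deposit into water and compare with
the package's closed-form aperture-fluence reference:

```r
phantom <- make_water_cube(41, 1, 90)         # 41³ voxels, SSD 90 cm
dose    <- deposit(run$store, phantom, attenuation_model())
dose
#> Dose grid: 41 x 41 x 41 voxels
#>   max dose: 5.42581e-15 Gy/history-equivalent
#>   histories equivalent: 3904600
#>   median rel. sigma (>50% voxels): 3.24 %

oracle <- analytic_aperture_dose(phantom, jaws, model$spectrum,
                                 focal_spot_sigma = model$focal_spot_sigma)
g <- gamma3d(oracle, dose, comparison_criteria(2, 2, 10))
sprintf("gamma 2%%/2mm pass: %.1f%% over %d voxels", g$pass_rate, g$n_evaluated)
#> "gamma 2%/2mm pass: 85.8% over 4494 voxels"
rmsd_percent(oracle, dose, 10)
#> 1.62
```

At this demonstration size the comparison is statistics-limited (3%
median uncertainty). Sizing the run with
`estimate_required_histories(dose, 0.01)` — the usual 1%-uncertainty
target — and pooling batches with `sum_dose(..., "histories")` brings the
same comparison above 99% gamma pass; that full-size run is what
`scripts/acceptance.R` performs. Dynamic plans go through `load_plan()` /
`collimate_dynamic()` (or `run_pipeline()` end to end), and
`to_gray()` + `sb_weighted_imrt()` / `sb_per_subfield()` handle absolute
dose. A thin CLI over the same functions lives at `inst/cli/fajtrace`.

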