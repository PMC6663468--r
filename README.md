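# motoret

Desk-scale cryo-electron-tomography analysis of the spirochetal flagellar
motor, in R.

Spirochetes such as *Borrelia burgdorferi* drive their periplasmic flagella
with unusually large motors: a 46-fold symmetric C-ring (the rotor's
cytoplasmic FliG/FliM/FliN ring), a spirochete-specific periplasmic collar
with 16-fold symmetry, and up to 16 membrane-embedded MotA/MotB stator
units arranged on an 80 nm ring around the C-ring. Two quantities tie the
motor's structure to its mechanics:

* **stator occupancy** — the fraction of the 16 stator sites that carry
  stator density, estimated by focused classification of the per-site
  subvolumes: occupancy = n(occupied class) / n(total sites), with
  "not sure" sites kept in the denominator;
* **C-ring tilt** — the angle between the C-ring wall and the rotation
  axis, measured by applying 16-fold symmetry, taking an axial
  cross-section, and fitting an ellipse to the C-ring density; the tilt of
  the major axis from the rotation axis is the readout. Wild-type motors
  (full occupancy, full proton flux) sit near 1.8°, stator-less motors
  relax to 7.8°, and proton-channel point mutants and uncoupler-treated
  cells fall in between.

The package implements the full analysis chain needed to measure both on
3D density volumes, together with a synthetic-data generator that builds
strain-specific motor phantoms and noisy, missing-wedge-filtered
subtomogram ensembles with complete ground truth:

* `volume()` / `read_volume()` / `write_volume()` — MRC2014 I/O and the
  coordinate/pose conventions (`pose()`), plus TSV particle tables
  (`read_particles()`, `write_particles()`);
* `strain_presets()`, `build_motor_phantom()`, `simulate_ensemble()` —
  parametric motor phantoms (WT, motB-D24E, motB-D24N, ΔmotB,
  CCCP-treated) and ensemble simulation at configurable SNR under a ±60°
  missing wedge;
* `wedge_mask()`, `constrained_cc()`, `align_particle()`,
  `fourier_average()`, `split_half_fsc()` — missing-wedge-constrained
  alignment, Fourier-space averaging with per-voxel coverage
  normalization, and half-set FSC resolution estimation;
* `angular_power_spectrum()`, `detect_symmetry_order()`, `symmetrize()` —
  rotational-symmetry analysis on cylindrical shells;
* `extract_site_subvolumes()`, `focused_align_sites()`,
  `classify_sites()`, `estimate_occupancy()`, `analyze_stator_sites()` —
  the stator-site occupancy pipeline;
* `radial_profile()`, `measure_ring_diameter()`, `cring_tilt_angle()`,
  `unroll_map()` — ring-geometry measurements;
* `run_strain()`, `compare_strains()` — the per-strain pipeline and the
  cross-strain comparison table.

## Worked example

```r
library(motoret)

presets <- strain_presets()
presets$WT
#> <strain_config> WT: C-ring 46-fold (r 28 -> 28.3 nm, tilt 1.8 deg), 16 stator sites (r 40 nm, p = 0.97 per site)

# noiseless WT phantom on the default 96^3 grid (1.25 nm voxels)
wt <- build_motor_phantom(presets$WT, occupancy_flags = rep(TRUE, 16))

# rotational symmetry of the C-ring and of the stator ring
detect_symmetry_order(angular_power_spectrum(wt, c(24, 32, -15, -4)))
#> [1] 46
detect_symmetry_order(angular_power_spectrum(wt, c(34, 46, -8, 10)))
#> [1] 16

# ring diameters from radial-profile peaks (nm)
measure_ring_diameter(radial_profile(wt, c(-15, -12)), c(24, 34))  # C-ring bottom
#> [1] 55.80696
measure_ring_diameter(radial_profile(wt, c(-7, 1)), c(34, 46))     # stator ring
#> [1] 80.66218

# C-ring tilt of the stator-less mutant: 16-fold symmetrize + ellipse fit
cring_tilt_angle(build_motor_phantom(presets$dmotB))
#> <tilt_result> C-ring tilt 8.01 deg (left 8.01, right 8.01)
```

The numbers are the phantom-encoded truths recovered by measurement: the
C-ring bottom diameter is 2 × 28 nm (one voxel of discretization), the
stator ring 2 × 40 nm, and the ΔmotB wall tilt 7.8° within the estimator's
sub-degree accuracy.

An end-to-end noisy run (simulate → average → symmetry → classify →
occupancy → tilt) for one strain:

```r
rep <- run_strain(list(strain = "D24E", n_motors = 16, box_voxels = 80,
                       snr = 0.5), seed = 42)
rep
#> <strain_report> D24E (16 motors, SNR 0.5, seed 42)
#>   symmetry: C-ring 45-fold, collar/stator 16-fold
#>   occupancy: 62.9% (~10.1 stators/motor; 161 occ / 94 empty / 1 amb)
#>   C-ring tilt: 3.25 deg
#>   diameters: bottom 55.9 nm, top 56.9 nm, stator 80.4 nm
#>   FSC resolution: 0.167 (0.5) / 0.212 (0.143) cycles/nm
```

The D24E preset plants exactly 10 of 16 stators (62.5%) and a 3.2° wall
tilt; both come back within the estimator noise at this small ensemble
size (at 32 motors the C-ring order is detected as exactly 46 — see the
vignette for what ensemble size buys).

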