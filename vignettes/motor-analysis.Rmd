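---
title: "Measuring stator occupancy and C-ring tilt in flagellar motor tomograms"
author: "motoret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring stator occupancy and C-ring tilt in flagellar motor tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Cryo-electron tomography records 3D density of flagellar motors in intact
spirochete cells, but each subtomogram is noisy and incomplete: the tilt
series only spans ±60°, so a wedge-shaped region of Fourier space is never
sampled. Two structural readouts of the torque-generating machinery are of
interest:

* **stator occupancy** — how many of the 16 collar-defined stator sites
  around the motor actually hold a MotA/MotB unit. This responds to the
  proton gradient: wild type sits near 97%, proton-channel point mutants
  (motB-D24E, motB-D24N) drop to ~10 and ~7 units per motor, and the
  ΔmotB deletion has none.
* **C-ring tilt** — the angle between the cytoplasmic C-ring wall and the
  rotation axis. The stator-less motor relaxes to ~7.8°; full stator
  occupancy plus proton flux pulls the wall nearly parallel to the axis
  (~1.8°), with mutants and uncoupler-treated (CCCP) motors in between.

This package implements the measurement chain for both quantities and a
synthetic-data generator whose phantoms encode the published geometry, so
every estimator can be validated against known ground truth.

# Coordinate and pose conventions

One convention is used everywhere (see `?pose`):

* right-handed frame, z along the motor rotation axis pointing from the
  C-ring toward the hook, origin at the MS-ring centre; the C-ring
  occupies negative z;
* voxels are 0-based with centres at integer coordinates; a `volume`
  carries `voxel_size_nm` and the `origin_voxel` of the axis centre;
* Euler angles are ZYZ intrinsic, degrees, normalized to [−180°, 180°);
  a pose applies the rotation about the origin first, then the shift;
* a *stored* pose (particle table, alignment result, ground truth) is
  always the alignment transform: applying it to the particle brings the
  particle into the canonical frame. Interpolation is trilinear with zero
  fill outside the grid.

# The motor phantom

`build_motor_phantom()` renders a motor as a sum of isotropic Gaussian
blobs:

* the C-ring: `n_cring = 46` subunits, each a 1 nm-spaced stack of
  σ = 1 nm blobs tracing the frustum wall. The wall rises 11 nm from a
  bottom radius of 28 nm and leans outward by the strain's tilt angle, so
  the top radius is `28 + 11·tan(tilt)`. The wall height of 11 nm is the
  one free geometric parameter; it is fixed so that the preset tilt
  angles reproduce the published top diameters (tan 7.8° · 11 ≈ 1.5 nm
  gives a 59 nm top for the stator-less motor; tan 1.8° · 11 ≈ 0.35 nm
  gives ≈56.7 ≈ 57 nm for wild type);
* the collar: 16 blobs (σ = 2 nm) at radius 33 nm above the membrane;
* stators: one σ = 2.5 nm blob per occupied site at radius 40 nm, just
  below the membrane (the ~8 nm cytoplasmic portion is the classified
  density; an optional second, periplasmic lobe can be enabled);
* MS-ring, rod, and an inner-membrane slab (a Gaussian z-profile,
  constant in x-y, so it contributes no angular structure).

Presets (`strain_presets()`): WT (tilt 1.8°, per-site Bernoulli
probability 0.97), D24E (3.2°, exactly 10/16), D24N (6.6°, 7/16), dmotB
(7.8°, 0/16), CCCP (5.1°, 16/16). Fixed counts are used where the source
data report a per-motor number, a probability where they report a rate;
where the published record rounds the same quantity two ways (e.g. "~10
per motor" alongside a coarser percentage), the presets encode the exact
per-motor count (10/16 = 62.5%, 7/16 = 43.75%), since that is the
quantity the phantom has to realize site by site.

The default grid is 96³ voxels at 1.25 nm/voxel (120 nm field): it
contains the 80 nm stator ring with margin while keeping every FFT
desk-scale. Amplitudes are arbitrary density units; all estimators are
scale-invariant.

# The simulator and what it does (not) emulate

`simulate_ensemble()` draws, per motor: occupancy flags, a random azimuth
about z (uniform in [0°, 360°)), a small pose jitter (each Euler angle
uniform in ±2°, shifts uniform in ±1 voxel), applies the ±60° missing
wedge *in the lab frame* by multiplying the Fourier transform with the
binary wedge mask, and adds white Gaussian noise scaled so that
signal-variance/noise-variance inside a cylindrical mask over the motor
equals the requested SNR.

The random azimuth is part of the initial pose guess (a picker knows
roughly how the motor sits in the tomogram), while the jitter is not: the
jitter is what alignment has to recover. The azimuth matters beyond
realism — because the wedge is fixed in the lab frame, particles at
different azimuths carry differently oriented wedges, and the pooled
Fourier coverage of the ensemble average fills in everything except the
polar double cone around the tilt-invariant z axis. Without it, the
common missing wedge imprints a strong 2-fold anisotropy on the average
that can defeat symmetry detection.

Deliberately *not* modelled (out of scope): projection/back-projection
reconstruction (the wedge is applied directly in Fourier space, which
reproduces the leading-order artifact), CTF, detector differences, dose
damage, membrane curvature, conformational heterogeneity beyond
occupancy, and molecular detail of the stator. Passing tests on these
phantoms therefore demonstrate correctness of the estimators under the
stated noise/wedge model, not performance on real tomograms — in real
data, alignment references, mask placement and contamination are all
harder.

# Missing-wedge machinery

`wedge_mask()` evaluates the coverage condition analytically on the
integer frequency grid: frequency k is covered iff some tilt in the range
satisfies k · b(α) = 0, with b(α) the beam direction at tilt α. The mask
is exactly binary, Hermitian-symmetric, and covers DC. Rotated supports
(for posed particles) are obtained by evaluating the same condition at
rotated frequency coordinates rather than by resampling the mask — the
result stays exactly binary, so per-voxel coverage counts are integers
and conservation checks are exact. A useful analytic anchor: over the
Nyquist ball the ±60° wedge covers exactly 120/180 = 2/3 of frequencies
(on the full cube the fraction is ~0.71 because the cube's corners
over-weight the diagonal sectors — the 2/3 figure is a property of the
ball).

`fourier_average()` rotates each particle (and its wedge support) to the
common frame, accumulates Fourier terms over the support, and divides by
the per-voxel coverage count, zeroing never-covered voxels.
`split_half_fsc()` correlates two seeded random half-averages per
one-voxel frequency shell, restricted to voxels covered in both halves;
`resolution_at()` interpolates the first downward threshold crossing (DC
shell excluded) and returns Nyquist if there is none.

# Alignment

`align_particle()` does an exhaustive search over a rotation grid
(rotation about the rod axis capped by `max_axis_rot_deg`, optional
off-axis tilt) times all integer shifts, then one refinement pass at half
the angular step; ties break to the lexicographically smallest pose, so
the result is fully deterministic.

Two numerical choices matter:

* scores are evaluated in the **particle frame**: the full-band reference
  is rotated onto each candidate pose and compared inside the particle's
  fixed wedge support. Rotating the wedge-filtered particle instead would
  leak a few percent of its energy across its sharp Fourier-support
  edges at every non-identity rotation — a penalty that can exceed the
  genuine mismatch signal for smooth objects and bias the argmax toward
  the identity;
* a Gaussian low-pass (default cutoff 1/(4 voxels)) is applied to *both*
  volumes during scoring, so a perfect match scores exactly 1 and the
  high frequencies most affected by interpolation carry little weight.

All integer shifts are scored at once per rotation through the Fourier
correlation theorem (one inverse FFT gives the full shift map).

# Symmetry analysis

`angular_power_spectrum()` resamples a cylindrical shell (default C-ring
shell r ∈ [24, 32] nm; collar/stator shell r ∈ [34, 46] nm — both bracket
the published diameters) onto a θ × z × r grid with 4·n_max angular
samples (a 2× Nyquist margin for order 60 candidates), averages over z
and r, and Fourier-transforms in θ. Powers are reported as shares of the
total non-DC angular power, which makes detection invariant to positive
rescaling.

`detect_symmetry_order()` resolves the divisor/harmonic ambiguity with a
fundamental-plus-half-first-harmonic score: a ring of N subunits excites
orders N, 2N, … but never divisors, so the score
`power(m) + power(2m)/2` is maximized at the true N even when a divisor
shows incidental power. The winner is declared only if its power exceeds
3× the median power over candidates; otherwise 0 ("no symmetry") is
returned. `symmetrize()` averages the volume over the n rotations about
z.

# Stator-site classification and occupancy

`analyze_stator_sites()` chains the three steps:

1. **extraction** — for site k the motor is brought to the canonical
   frame and rotated by −k·22.5°, so every site lands at the canonical
   stator position (40, 0, −3 nm); a 16 nm box is cropped there. All
   sites of all motors share one frame.
2. **focused alignment** — each site is locally aligned against the
   pooled site average under a spherical mask, with the rod-axis rotation
   capped below 2° (the focused-classification constraint) and ±1 voxel
   shifts. This step removes the pose jitter's effect on the site centre;
   without it a few percent of genuinely occupied sites fall into the
   ambiguous band at SNR 0.5.
3. **classification** — each site is scored by its mean density inside a
   6 nm sphere at the canonical stator position (the ~8 nm cytoplasmic
   portion fits inside) *minus* the mean inside an identical background
   sphere midway between neighbouring sites at the same radius and
   height. The background subtraction cancels the membrane slab and any
   radially symmetric background, so empty sites score near zero in
   expectation.

A two-component 1D Gaussian mixture is then fitted to the pooled scores
by EM from deterministic starts: the 10th/90th percentile init, an
extreme-anchored init, and the parameters of the best hard threshold
split found by an exhaustive scan. The last start matters for very
unbalanced mixtures (e.g. 8 empty sites among 512): plain EM can settle
in a local optimum whose low component absorbs the occupied cluster's
lower shoulder. The best-likelihood fit wins; the split is accepted only
if it beats a single Gaussian by BIC, otherwise the scores are treated as
unimodal and assigned collectively (occupied if the mean score exceeds
twice the score sd — meaningful because scores are background-subtracted
— else empty). With an accepted split, a site is `occupied` if its
posterior for the high component is ≥ 0.8, `empty` if ≤ 0.2, `ambiguous`
otherwise. Identical scores short-circuit to all-ambiguous.

`estimate_occupancy()` divides the occupied count by the *total* count —
ambiguous sites stay in the denominator, because the source procedure
divides the occupied-class particle number by the total particle number —
and multiplies by 16 for the mean stators per motor.

# C-ring tilt

`cring_tilt_angle()` follows the map-based procedure: apply 16-fold
symmetry; resample the axial cross-section plane at 4× finer than the
voxel spacing, averaged over a thin y slab (half-width one voxel); per
wall (left/right of the axis) keep samples inside r ∈ [24, 34] nm and the
wall's z range with the top 2 nm excluded (that cap is where the FliG-N
density sits in real maps, and the quoted procedure excludes it); keep
samples above the 0.75 density quantile of the window; fit an ellipse by
second moments weighted with the density *in excess of the threshold*;
report the angle between the major axis and the rotation-axis direction,
averaged over the two walls, in [0°, 90°].

The excess-over-threshold weighting is deliberate: blob tails from the
excluded cap region barely clear the threshold and would otherwise drag
the top end of the wall outward, inflating large tilts by ~0.5°. With it
the estimator is accurate to ~0.2° over the full preset range and to
better than 1° at 45°. The "Y-axis" of the published angle definition is
read as the rotation-axis direction in the cross-section plane, which
matches the described relaxation of the wall *away from the rotation
axis*. Moments were chosen over an algebraic conic fit for robustness on
blocky thresholded regions; the two agree within 0.5° on noiseless
phantoms (cross-checked in the tests) and a left/right wall discrepancy
above 2° raises a quality flag.

`radial_profile()` and `measure_ring_diameter()` provide the diameter
readouts (cylindrical average in a z slab; parabolic sub-bin peak
interpolation). `unroll_map()` resamples onto θ × z × r for the
side-by-side ring displays.

# Pipeline, problem sizes, reproducibility

`run_strain()` executes simulate → average → symmetry → FSC → site
classification → tilt → diameters and returns a structured report;
`compare_strains()` tabulates several reports and checks the expected
tilt ordering (WT < D24E < D24N < dmotB). Reports are byte-identical for
identical (config, seed).

Default study conditions follow the published setting where one exists
(±60° wedge with 2° tilt steps, i.e. 61 images; 16 sites; preset
occupancies and tilts; 46-fold C-ring). Free desk-scale choices: 32
motors per ensemble at SNR 0.5 for the noisy recovery analyses, and the
96³ × 1.25 nm grid (the test suite uses 80³ for its noisy-ensemble cases,
a 100 nm field that still leaves a ≥20% margin around the stator ring —
chosen as the package's own smallest faithful size). Pose jitter defaults
(±2°, ±1 voxel) keep the truth within the focused search range, which is
the regime the focused-classification constraint (<2° about the rod)
presumes.

# Known limitations

* The generator's noise is white and Gaussian; real tomograms have
  coloured noise, CTF modulation and reconstruction artifacts beyond the
  missing wedge.
* The angular power spectrum needs the rotation axis centred; a miscentred
  map leaks power into low orders. Within the pipeline, maps come out of
  averaging centred by construction.
* `align_particle()`'s exhaustive grid is meant for the small focused
  searches used here; a global 3-Euler search at fine steps would be
  slow (the off-axis tilt azimuth is sampled at 45° on purpose).
* The occupancy estimator classifies sites independently; it does not
  model per-motor correlations, and at occupancies very near 0 or 1 the
  mixture degenerates to the (collective) unimodal rule.
* The MRC reader supports little-endian modes 0/1/2/6 with the standard
  axis mappings — sufficient for interchange with the common cryo-EM
  tools, not a full implementation of every header extension.
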