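---
title: "Measuring the endothelial surface layer and red-blood-cell flow in microvessels-on-chip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the endothelial surface layer and red-blood-cell flow in microvessels-on-chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The measurement problem

Endothelial cells cultured inside square PDMS microchannels form a confluent
monolayer whose luminal face carries a glycosaminoglycan-rich coat, the
endothelial surface layer (ESL, or glycocalyx). Both the cell bodies and the
ESL narrow the lumen available to flow, and both matter for the hydrodynamics
of blood perfused through the device. `vesselchip` quantifies this system
from two kinds of confocal acquisitions:

* **XYZ stacks** of the lectin-stained ESL (raster scans, typically
  0.225 µm/pixel laterally, 0.5–1 µm between z-planes), from which we
  measure the ESL thickness and the topography of the apical membrane;
* **XYT time-lapses** at the channel mid-height (line scans, 0.444 µm/pixel,
  ~300 frames/s), from which we measure red-blood-cell (RBC) velocity
  profiles, the near-wall cell-free layer (CFL), the cross-stream
  distribution of cells, and the in-channel hematocrit.

The measured lumen reduction feeds an exact rectangular-duct laminar flow
model, and the model's centreline velocity is confronted with the tracked
RBC velocities — the pipeline's central consistency check.

Because raw microscope data cannot ship with the package, a synthetic-data
module generates both kinds of stacks with known ground truth; every
estimator is validated by recovery against that truth.

# ESL thickness by deconvolved FWHM

The ESL appears in an XY plane as a thin bright band along the channel wall.
Its thickness is defined operationally as the full width at half maximum
(FWHM) of intensity profiles drawn across the band, *after* deconvolution of
the stack by the microscope point-spread function (PSF); without
deconvolution the width of a sub-micron layer is dominated by the optics.

Implementation choices:

* **PSF model** (`generate_psf()`): a scalar Gaussian approximation of the
  confocal PSF, with lateral sigma `0.21 λ/NA` and axial sigma
  `0.66 λ n/NA²`. The exact diffraction integral is not needed because the
  deconvolution step is validated end-to-end: a synthetic 500 nm latex bead
  blurred by the PSF must measure 0.5 µm ± 1 pixel after deconvolution, the
  same calibration used at the microscope. This holds here for bead
  diameters 0.4–1.0 µm.
* **Deconvolution** (`deconvolve()`): Richardson–Lucy with reflective
  padding by one PSF half-width, default 15 iterations, optional damping of
  the multiplicative update for noisy data. Output is non-negative and
  conserves total intensity to about 1% when the structure is clear of the
  stack boundary.
* **Profiles** (`extract_profiles()`): the band's ridge is located per image
  row as the smoothed intensity argmax; profiles are drawn along the local
  ridge normal (bilinear interpolation), span at least 3 µm, and are placed
  by seeded uniform sampling over planes and ridge positions with ≥ 1 µm
  spacing. Placement in the original experiment is not described; systematic
  seeded sampling makes the measurement reproducible.
* **FWHM** (`fwhm()`): background is the median of the outer 20% of profile
  samples (the half level needs a baseline, which the original description
  leaves implicit); crossings are located by linear interpolation. Profiles
  whose peak is not bracketed by half-level crossings on both sides (ramps,
  edge peaks) are rejected and excluded from aggregation. The estimator is
  invariant under affine intensity rescaling.

On sampled top-hat profiles the interpolated FWHM carries a worst-case
half-pixel phase error; the package's tests pin this against a brute-force
enumeration over sampling phases. End-to-end (generate → blur → noise →
deconvolve → measure), imposed mean thicknesses across 0.4–1.2 µm are
recovered within a few percent, comfortably inside the 15% the test suite
requires — for shells at least two lateral pixels thick and at the package's
default acquisition geometry.

# Lumen topography

The apical membrane surface is extracted from an XYZ stack by the classical
edge-detect → threshold → skeletonize recipe, applied along the wall normal:
a Sobel-type gradient magnitude is thresholded with Otsu's method and, per
lateral grid cell, the innermost (lumen-facing) supra-threshold run is
reduced to its medial position. The threshold is computed globally over the
stack rather than per z-slice: slices far from the membrane contain no
signal, and a per-slice threshold there would pass pure noise. Gaps are
filled by nearest-neighbour interpolation and flagged; more than 20% missing
cells aborts the extraction. Heights are zero-referenced to the lowest
point, so `h_mean` is the mean membrane height above the inter-cell valleys
and excludes the ESL itself.

Summary statistics:

* `roughness_stats()`: `h_mean` (mean of the zero-referenced map) and `R_q`
  (rms deviation about the mean plane — the standard roughness definition;
  whether the original analysis referenced the mean plane or the zero level
  is not stated, and the choice is recorded in the output).
* `hump_metrics()`: cell bodies appear as humps; peaks are detected on a
  2 µm-smoothed map with an 8 µm non-maximum-suppression radius, and
  measured on a lightly (0.5 µm) smoothed map so detection smoothing does
  not flatten the amplitudes. Height is peak minus the 5th percentile of a
  local window, width is the mean of the two axis-aligned half-prominence
  widths, spacing is the mean nearest-neighbour peak distance.
* `boundary_shift()`: for laminar flow over small-slope roughness the wall
  acts as a smooth no-slip plane displaced into the flow by
  `δ = 2π R_q²/d`. With the measured `R_q = 0.6` µm and `d = 35` µm this
  gives 0.065 µm, reproducing the reported shift; the formula's scalings
  (`∝ R_q²`, `∝ 1/d`) are tested explicitly.

# The effective lumen and the duct flow model

`channel_geometry()` stacks the lumen corrections: each wall of the bare
square channel (side `S₀`, here 32 µm) is displaced inward by the
peripheral cell-body thickness `h_peri`, the mean membrane height `h_mean`,
the roughness shift `δ`, and optionally the ESL thickness `h_ESL`;
`effective_side()` returns `S₀ − 2(h_peri + h_mean + δ [+ h_ESL])`. With the
measured layer values this yields 27.33 µm against the reported
27.4 ± 1.07 µm.

`duct_flow_model()` evaluates the exact Fourier series for pressure-driven
laminar flow in a rectangular duct, scaled so the cross-sectional integral
equals the imposed per-channel flow rate (the 1 µL/min network feed splits
equally over 16 parallel channels). Numerical choices: 101 odd series terms
(the max/mean ratio is converged to < 5·10⁻⁴ by 51 terms), cosh ratios
evaluated via exponentials to avoid overflow, and an independent
finite-difference Poisson solve in the test suite that must agree pointwise
to < 0.5%. For a square duct the centreline-to-mean velocity ratio is
2.0962, so `vmax_theory()` predicts
`V_max = 2.0962 · Q/(16 S)` — about 2909 µm/s at the 27.4 µm effective
lumen, inside the measured 2950 ± 200 µm/s.

`wall_shear_stress()` uses the axial force balance (pressure gradient ×
area = mean shear × perimeter), with the pressure gradient known
analytically from the flow rate. The culture-medium viscosity is not part
of the experimental record; the default 0.75 mPa·s (medium at 37 °C) puts
the seeding-flow shear at ~0.1 Pa, the order of the nominal 0.2 Pa — the
statement is order-of-magnitude only and the viscosity is configurable.

# RBC tracking

The time-lapse pipeline mirrors a standard spot-tracking workflow:

1. `preblur()` — Gaussian smoothing (radius 3 px) so each cell carries one
   intensity maximum.
2. `detect()` — difference-of-Gaussians band-pass tuned to the apparent
   cell diameter (σ₁ = d/(2√2), σ₂ = 1.6 σ₁), local maxima above a
   threshold, sub-pixel refinement. Two departures from the naive recipe
   proved necessary and are defaults: the per-pixel *temporal mean* (the
   static wall bands) is subtracted before filtering — otherwise the bright
   bands pull the lateral position of near-wall cells and flatten the
   fitted profile — and the sub-pixel step uses a baseline-subtracted
   centroid over a ±4 px window, because the broad DoG response makes a
   3-point quadratic fragile. Detections within 2.5 µm of the wall bands or
   half a spot diameter of the frame edges are discarded.
3. `link()` — gated linear-assignment linking: per frame pair the exact
   maximum-weight bipartite matching under a hard displacement gate
   (weights `gate² − d²`), no merging or splitting, optional gap bridging
   with a proportionally enlarged gate. Because channel flow is
   unidirectional, links with more than 0.5 µm backward streamwise
   displacement are excluded — without this, the track of a cell leaving
   the field of view captures the next cell upstream (the backward distance
   is smaller, so plain LAP prefers it) and speeds are systematically
   underestimated. Tracks shorter than 10 detections are dropped.
4. `profile_and_fit()` — per-track mean lateral position and mean speed are
   fitted with `V(y) = V_max (1 − (y/y_wall)²)`, which is linear in
   `(1, y²)`. Tracks whose frame-to-frame speed dispersion exceeds 20% of
   their mean are excluded first: advected tracers move at essentially
   constant speed, so a large dispersion flags linking errors. The
   centreline statistic (mean ± sd within ±1 µm of the axis) is reported
   alongside.

The y origin is the midpoint of the two wall-band ridges from the temporal
mean projection (`locate_walls()`), shared with the flow-structure module.
On synthetic duct flow at the default acquisition scale the fitted `V_max`
is within ~1% of the model value (the mid-height duct profile is not
exactly parabolic; fitting a parabola to it over the occupied span biases
the apex by < 0.5% on its own).

# Flow structure

`t_project()` computes the per-pixel temporal mean and population standard
deviation. The mean retains static structure (the stained ESL at the
walls); the standard deviation responds only to fluctuations (the
accumulated RBC paths).

`cfl_thickness()` measures, at each of several streamwise positions (after
averaging over a 10 µm window to suppress the ~10 µm frame-advection
modulation):

* `w_ch` — the inner channel width, as the distance between the two
  wall-band peak centres of the mean-projection profile, each centre taken
  as the midpoint of its half-level crossings;
* `w_RBC` — the RBC column width, at mid-height of the central bump of the
  *temporal-variance* profile (the variance, unlike the standard deviation,
  is linear in local cell occupancy) after the profile is deconvolved in 1D
  by the lateral cell kernel (Gaussian, σ = spot diameter/4). Two biases
  motivate the deconvolution: a cell of finite size smears the column edge
  outward by its own radius, and slow near-wall cells are over-weighted by
  residence time; both shift the raw mid-height crossing outward by
  0.7–1.5 µm, and the second breaks the measurement entirely when the
  column nearly fills the channel (the profile becomes edge-peaked).
  Deconvolution restores a sharp edge at the cell-centre column boundary;
  the half-level crossings are then scanned inward from the walls, with the
  column level taken as the median of the supra-threshold core and the
  background as the 10th percentile between the walls, so both dome- and
  bathtub-shaped columns are handled.

The depleted-layer thickness is `h_dep = (w_ch − w_RBC)/2`; adding the mean
ESL thickness gives the full cell-free layer between the apical membrane
and the cell column (3.8 + 0.67 ≈ 4.5 µm for the reported values). The
recovery tests require imposed depletions from 2 pixels up to several µm to
come back within ±0.5 µm.

`lateral_distribution()` bins trajectory mean positions into 30 adjacent
1 µm bins centred on the axis, converts counts to a linear number density
(`N_i/Δy`) and normalizes by the average density (`N_tot/w_ch`), so a
uniform occupancy has density 1 by construction. Mode detection runs on a
lightly smoothed density and reports the two strongest well-separated
maxima, their separation and the peak-to-average contrast.

`hematocrit()` implements the counting estimator
`Ht(%) = N v/(Q_channel ΔT) × 100` with consistent units (fL, µL/min, s).
`simulate_rbc_counts()` emulates the multi-plane counting protocol (7 XY
planes spanning the height) by tiling the cross-section into slabs and
drawing Poisson counts with mean `(Ht/v)·Q_slab·ΔT`; the estimator recovers
an imposed volume fraction within the Poisson noise, testing the counting
logic and the duct quadrature together. `cumulated_area_check()` is the
book-keeping that justifies reading structure in the projections: the
travelling cells cover the imaged section tens of times over.

# What the generator emulates — and what it does not

`make_esl_stack()` drapes a fluorescent shell of locally Normal thickness
(clipped positive) over a membrane surface built as Gaussian humps on a
jittered square lattice above a flat periphery, rasterizes it with exact
partial-volume coverage along the wall normal (the analytic limit of
supersample-and-average; lateral axes are sampled on the pixel grid where
the thickness field is defined), applies the PSF by FFT convolution, and
adds Poisson shot noise on a scaled intensity plus Gaussian read noise —
the standard confocal detection model. Shells thinner than one voxel along
the normal generate a warning but proceed (sub-resolution shells are a
legitimate test case). `make_bead_stack()` rasterizes a solid sphere with
4× supersampled partial-area coverage in-plane but *point samples* each
z-plane: a confocal page samples the focal plane, and axial blur is the
PSF's job — axially box-averaged beads would measure systematically
narrow.

`make_rbc_timelapse()` draws one lateral position per cell (uniform over
the non-depleted core, or a symmetric two-Gaussian mixture), advects each
cell at the mid-height duct velocity for its position, and renders
Gaussian-profile discs (effective radius √(40/π) ≈ 3.57 µm, the plan-view
area of an RBC) plus two static wall bands. Defaults reproduce the
acquisition: 512 × 100 px at 0.444 µm/px, 300 frames/s, 3 s, 400 cells,
27 µm inner width, 3.8 µm depletion, 8.5 µm mode separation with 2.7 µm
component sd — chosen so the realized density peaks reach about twice the
average, as observed. Ground truth (per-frame positions, per-cell speed,
surface height, thickness and hump-centre tables) always accompanies the
stacks, and every recovery test compares against it rather than against
constants.

Deliberately *not* simulated: RBC deformation, tumbling, and cell–cell
hydrodynamics (the lateral structure is imposed, not emergent — the
generator tests measurement, not physics); photobleaching; non-separable
or vectorial PSFs; flow off the mid-height plane. Consequently, passing
recovery tests demonstrates that the estimators are unbiased for data with
the assumed statistical structure at the stated acquisition settings; they
cannot certify behaviour under strong cell overlap (the detector is
specified for the dilute regime), optical aberrations, or genuinely
non-stationary flow.

# Problem sizes and reproducibility

All randomness flows through explicit integer seeds in the spec objects
(`surface_spec`, `shell_spec`, `noise_spec`, `flow_spec`), and seeded
generation is bit-reproducible; the RNG state of the caller is left
untouched. The test suite runs the tracking recovery at the full
acquisition scale (two 900-frame, 512 × 100 px sequences) and the ESL
recovery on 20 µm wall patches with 140 profiles, sizes chosen to keep a
complete run within a few minutes on one CPU while leaving the statistical
power the tolerances need. The duct series uses 101 odd terms; the
finite-difference oracle a 201² grid; Richardson–Lucy defaults to 15
iterations (3D) and 60 (1D profile sharpening).

# Known limitations

* The duct model assumes equal flow splitting across the 16 parallel
  channels and rigid walls; no network hydraulic solver is included.
* The ESL measurement is restricted to XY planes (the lateral resolution is
  several-fold better than the axial one); XZ profiles are deliberately not
  offered.
* `hump_metrics()` assumes humps are resolvable as distinct local maxima;
  strongly merged cell bodies read as fewer, wider humps.
* The hematocrit estimator inherits the counting protocol's assumptions:
  every cell crossing the imaged planes is counted exactly once.
* Wall shear stress is only as good as the assumed medium viscosity.
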