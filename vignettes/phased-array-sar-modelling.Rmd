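---
title: "Modelling phased-array hyperthermia applicators: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phased-array hyperthermia applicators: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Locoregional hyperthermia heats deep-seated pelvic tumours with radiative
phased arrays operating between 60 and 130 MHz. At these frequencies the
wavelength in tissue is 30-60 cm, so an annular arrangement of antennas
produces a broad interference focus (roughly a quarter wavelength across)
that is steered by adjusting per-channel phases and amplitudes. Treatment
planning for such devices is only trustworthy if the simulated heating
characteristics — focus location and size, and the response of the specific
absorption rate (SAR) pattern to phase-amplitude and frequency steering —
match what quality-assurance (QA) measurements in tissue-equivalent phantoms
show.

`phasedheat` implements that simulation chain for four clinically used
devices: the AMC-2 double-waveguide system and the AMC-4/ALBA-4D
four-waveguide ring (70 MHz, water-filled 20 x 34 cm apertures), and the BSD
Sigma-30 and Sigma-60 annular dipole arrays (eight z-oriented dipoles on 30
and 58 cm rings). Each device is paired with the QA phantom its published
characterization used: elliptical saline or wallpaper-paste phantoms (24 x
36 cm cross section, optionally with an 8 x 8 cm fat-equivalent core), a
20 cm agarose cylinder, and the elliptical CDRH phantom (35 x 25 cm with a
2 cm fat layer).

## The model

The pipeline is: voxelize phantom and applicator into a uniform isotropic
grid of dielectric labels; solve Maxwell's curl equations per drive channel
with the finite-difference time-domain (FDTD) method until a single-frequency
steady state; extract the complex field phasor per channel for unit drive
amplitude and zero phase; superpose channels under a drive setting
(amplitude = sqrt of the power ratio, complex phase factor per channel);
convert to SAR via

SAR = sigma / (2 rho) |E|^2,

with peak-convention phasors (the 1/2 carries the time average); average
over 1 cm^3 cubes; and extract profiles along the published measurement
axes. Temperature-rise measurements convert to SAR through SAR = c dT/dt.
Focal steering phases for the Sigma-60 quadrant ring follow the distance
rule phi_i = 0.1 f (D_i - D_max) (f in MHz, D in cm), which reproduces every
console setting printed for the published benchmark grid.

### Discretization

* Standard staggered (Yee) leapfrog grid. Material voxels are cell-centered;
  each E component lies on the face between two voxels and its update
  coefficients use the arithmetic mean of sigma and eps_r over those two
  voxels — the conventional second-order interface treatment for this
  layout.
* Metal (waveguide walls, dipole arms) is a perfect-conductor label, not a
  finite conductivity: every E component touching a metal voxel is held at
  zero. At 60-130 MHz copper behaves as an ideal conductor for all purposes
  of this model.
* Time step: `courant_factor` (default 0.95) of the 3-D stability limit
  `dx / (c0 sqrt(3))`, rounded so that an integer number of steps spans one
  carrier period (the phasor extraction depends on that).
* Sources are lumped resistive voltage sources (semi-implicit Taflove
  update). Undriven channels keep the 50 Ohm resistor and therefore act as
  matched terminations, implementing the stated termination contract without
  modelling matching networks.
* The drive waveform is a raised-cosine-ramped sinusoid (3 carrier periods,
  continuous first derivative). Only the steady single-frequency response is
  used, so any smooth ramp is admissible; the ramp keeps the injected
  spectrum far inside the band the grid resolves.
* Steady state is detected from per-period discrete-Fourier phasors at seven
  monitor voxels (phantom center plus six axis-aligned points); the run
  converges when the largest per-period change of monitor |E| falls below
  `convergence_tol` (default 1e-3, relative to the largest monitor |E|).
  One further period is then integrated over the whole grid to produce the
  returned phasor volume, collocated at voxel centers.

### Absorbing boundaries

The grid is terminated by a 16-layer convolutional PML (CPML) behind a
one-voxel perfect-conductor shell. Grading is cubic-polynomial with
kappa_max = 8 and the standard opacity optimum for sigma_max. One parameter
required its own calibration: the complex-frequency-shift constant
alpha_max. Values around 0.05 S/m, customary in GHz-range work, put the CFS
pole two orders of magnitude above these carrier frequencies
(omega eps0 ~ 4e-3 S/m at 70 MHz), which turns the PML stretch nearly real
and collapses absorption (measured 1.8% reflection). The default here is
alpha_max = 0.002 S/m, which yields 0.0005-0.005% normal-incidence
reflection across all operating frequencies, grid spacings and background
media used by the scenarios.

### Numerical precision

Fields are single precision with flush-to-zero/denormals-are-zero enabled:
as the excitation wavefront decays into the PML it passes through the
subnormal float range, and hardware subnormal handling would otherwise
dominate the runtime by an order of magnitude. The 1-D validation shows the
discretization reproduces the closed-form lossy-medium attenuation constant
to 0.01% after grid-dispersion correction (0.02% against the continuum
value at 2.5 mm), so single precision is nowhere near the accuracy limit of
the model.

## Device modelling choices

Published geometry is followed wherever printed; the open details were
decided once, as follows, and are not tuning knobs:

* **Waveguide feeds.** Each water-filled guide (aperture w x 34 cm, depth
  12 cm) is fed by a z-directed line of resistive voltage sources at the
  transverse center, 3 cm from the back wall. Feed polarization is axial
  (z) for all four ring positions: the published four-channel interference
  focus requires co-polarized antennas, and these systems are built with
  the E field along the patient axis. The choke fin of the physical feed
  assembly is not modelled: its geometry is unpublished, an off-center fin
  would break the aperture symmetry that the measured profiles display, and
  the steady-state aperture field — not the feed detail — controls the SAR
  in the phantom.
* **Dipoles.** Eight z-oriented rods of one voxel cross section (the
  printed approximation is a thin cylindrical dipole; thin-wire behaviour
  at these wavelengths is insensitive to mm-scale radius), equally spaced
  at 45 degrees, grouped into four quadrant channels at +-22.5 degrees
  around top/bottom/left/right. Each dipole is driven at a central gap; on
  this staggered grid the minimal drivable gap is one free z-edge between
  the two arm tips (two voxels of separation), and that edge carries the
  50 Ohm lumped source.
* **Boluses.** Waveguide boluses are water slabs of the printed thickness
  and footprint between aperture and phantom (the phantom is re-painted
  after the slab, so the bolus conforms to the elliptical surface). The
  Sigma bolus is a water cylinder that ends exactly at the dipole ring: in
  the physical applicators the antennas sit at the bolus surface. Letting
  water extend behind the ring deepens the lateral standing-wave minima of
  the small-ring device by several percentage points and is not physical.
* **Densities and heat capacities.** Densities are not part of the printed
  record: 1000 kg/m^3 for muscle-equivalent media and water, 900 for
  fat-equivalent, 1400 for PVC. Normalized SAR profiles within a single
  medium are insensitive to rho. Heat capacities are the printed 4180 /
  2430 J/kg/degC where stated; deionized water takes 78 / 5e-4 S/m.
* **PVC shell.** The 2 mm shell is thinner than any practical voxel; it is
  represented as a one-voxel rind of PVC (eps_r 2.7, sigma 0). At 70 MHz a
  centimetre of low-permittivity lossless material is electrically thin
  (lambda/430), so the coarse-grid exaggeration of its thickness has little
  effect, which the grid-refinement checks confirm.
* **Phantom truncation.** The 115 cm saline phantoms are modelled at 60 cm
  length: with alpha ~ 9.5 Np/m in saline at 70 MHz, fields returning from
  the phantom ends influence the midplane by well under one percent. The
  50 cm inhomogeneous phantom and the CDRH phantom (60 cm, length not
  printed) are modelled in full.

## Mirror reuse and caching

Per-channel unit-drive fields are independent of the drive settings, so the
seven-phase AMC-2 family and the Sigma-60 frequency grid reuse channel
solves exactly; an in-session cache keyed by scenario, frequency and solver
configuration makes this automatic. For scenes whose label array is exactly
mirror symmetric (checked, not assumed), the bottom and left channels are
obtained by reflecting the solved top and right fields (positions reflected,
the E component along the mirror axis sign-flipped). This is exact for the
discrete operator, and the test suite verifies mirrored fields against
direct solves. The AMC-2 set-up is deliberately not mirrored: its top and
bottom boluses have different printed widths.

## Study conditions and problem sizes

The published simulations use 2.5 mm voxels. The routine validation runs in
this package use 10 mm voxels (with 5 mm and 2.5 mm available through
`resolution`), chosen as the scaled-down condition under which the full
five-scenario suite completes on a single CPU in well under half an hour.
The 1 cc averaging contract restricts spacings to divisors of 10 mm. At
10 mm, grids are roughly 10^6 cells and a channel solve takes 10-20 carrier
periods to converge. The headline quantities are resolution-stable: the
Sigma-30 minima move by under 2 mm and their level by under 0.2 percentage
points between 10 mm and 5 mm, and the AMC-4 focus sizes are stable within
the sub-voxel refinement error of the minima finder.

What passing at these conditions shows — and does not show: the scaled-down
grid reproduces interference structure, steering response and axial decay,
which are wavelength-scale phenomena; it under-resolves the 2 mm shell, the
exact rod radius and feed gap, and boundary-layer gradients within ~1 voxel
of material interfaces. Pointwise agreement with measured profiles near
phantom borders is additionally limited by the measurements themselves
(probe spacing, bolus contact), which is why profile comparisons report
interior statistics separately.

## Degenerate inputs and edge rules

* Rasterization is by voxel-center inclusion, boundary inclusive, with a
  sub-nanometre tolerance so printed dimensions that are exact voxel
  multiples land symmetrically; a primitive that misses the grid entirely
  is a warning no-op.
* A world point exactly between two voxel centers maps to the lower index.
* Profiles are restricted to phantom voxels; 1 cc averaging never crosses a
  medium interface (cube clipped to the voxel's own medium, mean over the
  clipped intersection), so it cannot manufacture gradients across the
  fat/muscle boundary.
* The 1 cc cube at 2.5 mm (4 voxels per axis) cannot be centered on a
  voxel; the two half-voxel-offset windows are averaged, which removes the
  half-voxel profile shift a single window would introduce.
* Focus metrics require two interior local minima flanking the central
  maximum; minima within 2 cm of the profile ends do not count (border
  effects), and a monotone profile reports an undefined focus rather than
  an error. Sub-voxel refinement is 3-point parabolic, with ties broken
  toward the center.
* The focal-phase rule rounds to integer degrees (consoles print integers);
  the exact values are returned alongside.

## Known limitations

* No thermal modelling: SAR is the endpoint, as in the QA comparisons.
* No phase-amplitude optimization; drives are data.
* Antenna feed networks, crosstalk and impedance matching are outside the
  model (undriven channels are ideal 50 Ohm loads); published evidence
  attributes part of the high-frequency measurement spread to exactly these
  effects.
* The lateral minimum level of the small-ring cylindrical set-up sits a few
  percentage points deeper in this model (about 48% of center) than the
  published narrative (~60%); the printed geometry leaves the bolus former
  and probe-averaging effects unconstrained, and the measured profile was
  acquired with 1.5 cm probe spacing after a five-minute heat-up, both of
  which fill in a narrow dip. The minima positions agree.
* Dispersive or temperature-dependent material properties are not
  modelled; each scenario uses the printed properties at its frequency.

## Reproducing the validation numbers

`scripts/acceptance.R` re-runs the three scenario families behind the
headline numbers (AMC-4 homogeneous focus sizes, Sigma-30 radial minima,
Sigma-60 axial decay) from scratch at 10 mm and writes them as JSON; the
test suite additionally checks the AMC-2 steering family, the AMC-4
inhomogeneous axial decay, and the quantitative solver properties
(closed-form attenuation, CPML reflection, superposition linearity,
reciprocity, rotation and mirror symmetry).
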