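---
title: "Monte Carlo methods behind fluorodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo methods behind fluorodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fluorodose` is a desk-scale toolkit for radiation-dose awareness in the
interventional radiology (IR) suite. It covers the computational chain a
mixed-reality dose display needs: (1) Monte Carlo estimation of the
patient's skin-dose distribution on a CT-derived voxel phantom under the
current fluoroscopic conditions; (2) an angular lookup table of scattered
air kerma in the room, precomputed over the C-arm gantry range, from which
a staff member's eye-lens dose rate at any tracked head position is
interpolated in real time; (3) an acquisition pipeline that recovers the
fluoroscopic conditions from console-screen images by template matching and
the patient-table position from temperature-corrected ultrasonic ranging;
and (4) a session orchestrator that turns condition and observer streams
into hologram-ready dose payloads. This vignette records the models, the
tunable parameters, the numerical choices, and the limits of what the test
suite demonstrates.

## Photon transport model

Transport covers 5–150 keV photons, the range relevant to fluoroscopy.
Cross sections for the six supported materials (air, lung, soft tissue,
bone, water, copper) are shipped as a CSV at the standard compilation grid
and interpolated log–log, which is positive by construction and accurate to
well under a percent between grid points in this range. Soft tissue and
lung share water-equivalent per-gram coefficients — the standard
simplification in dosimetry — and differ only through the CT-derived
density. The per-interaction partition (photoelectric / incoherent /
coherent) is derived from the closed-form Klein–Nishina total cross section
plus a small effective-Z parameterisation of the coherent part (see
`inst/scripts/make-xsec-table.R`); the partition steers interaction-type
sampling, while attenuation always uses the compiled total.

Free paths through the voxel phantom are sampled by Woodcock (delta)
tracking with an energy-dependent majorant over the materials present:
unbiased, geometry-free, and easy to verify — the Beer–Lambert test fires a
monoenergetic pencil beam into a homogeneous water slab and checks the
first-interaction depth distribution against `exp(-mu t)` at the 3-sigma
binomial level. Outside the phantom the room is a set of homogeneous
axis-aligned regions (air, a low-density carbon-fiber-like table slab,
concrete walls) with analytic exponential free paths and
distance-to-boundary handling. Walls reuse cortical-bone cross sections at
concrete density 2.3 g/cm^3 — a deliberate surrogate with similar effective
Z; no fluorescence is modeled.

Interactions: photoelectric absorption deposits the full photon energy
locally; Compton scattering samples the Klein–Nishina distribution by
Kahn's rejection method, deposits `E - E'` locally, and continues the
photon; coherent (Rayleigh) scatter is off by default, and when disabled
its share of the attenuation coefficient is excluded consistently so the
mean free path stays unbiased. Photons falling below the 5 keV cutoff
deposit locally and terminate. Secondary electrons are not transported
(kerma approximation): below 150 keV their CSDA range is well under a
millimeter, small against the 3 mm default voxel.

The tube spectrum is Kramers bremsstrahlung `(kVp - E)/E` hardened by the
copper filtration, binned at 1 keV; no tungsten characteristic lines and no
anode heel effect. The spectrum's `meanEnergy()` is the continuous
fluence-weighted mean of the closed form (Simpson quadrature), so thicker
filtration strictly raises it. Beam directions are sampled uniformly over
the collimated fov x fov square on the detector plane — a collimated-beam
model whose difference from uniform-in-solid-angle sampling is a cos^3
weighting below 1% at the 5.7 degree half-angle of the reference 20 cm
field.

## Estimators and uncertainty

Skin dose is scored with a **track-length collision-kerma estimator**:
every photon flight segment crossing a skin voxel contributes
`E * (mu_tr/rho) * L / V`. Under the kerma approximation this estimates
the same quantity as analog energy deposition but with far lower variance,
because every crossing photon contributes rather than only the few that
collide inside a 3 mm voxel; it is what lets a 1e7-photon run reach the
roughly 2% peak-voxel precision the acceptance suite checks (analog
scoring needs an order of magnitude more photons for the same precision at
this voxel size). Analog deposition is still tallied for the
energy-conservation check — emitted = deposited + escaped holds to
machine precision every run.

Room air kerma uses the same track-length estimator on a coarse lattice
(default 10 cm), scored in the open-air region; segments inside the phantom
bounding box, the table slab or the walls do not contribute (those voxels
are not air). Statistical uncertainty everywhere is the relative standard
error of the batch mean over `nBatches` (default 10) independent batches;
the documented precision statistic is the relative SE at the voxel of
maximum mean skin dose. Uncertainty follows 1/sqrt(n), which the suite
verifies by quadrupling the photon count.

The transport kernel has its own counter-seeded xoshiro256++ generator, so
a given `(seed, configuration)` reproduces every output bit-identically on
any platform, independent of R's RNG state.

## From per-photon scores to clinical quantities

MC scores are per source photon. `doseRateScale()` bridges to Gy/s as
`dose_per_photon x calibration(photons/mAs) x mA x duty`. The default
calibration of 2e10 photons/mAs into the collimated beam is a nominal
placeholder of the right order for a filtered tube at 76 kV; a deployment
would replace it with a site measurement. The pulse duty cycle defaults to
continuous (duty = 1); frame rate is recorded and only enters if a pulse
width is configured, since pulsed-mAs bookkeeping varies by vendor.

Eye-lens dose applies the scalar ICRP conversion 1.550 Gy/Gy to the air
kerma interpolated at the head position — exactly linear, with no
directional dependence, matching the practice of applying one scalar
factor.

## The angular air-dose table

A table is built per beam-condition fingerprint (kVp, filtration, field of
view, SID) on an angular grid spanning the full gantry range, lateral
-90..90 and cranio-caudal -30..30 degrees. The range is fixed; the step is
a free parameter defaulting to 15 degrees on both axes (13 x 5 = 65
nodes), a desk-feasible compromise — the scatter field varies smoothly in
gantry angle, and queries interpolate multilinearly (bilinear in angle,
trilinear in position), which is exact at nodes and bounded by neighboring
node values. Tube current and exposure time scale linearly at query time,
which is why one table per fingerprint suffices. Queries outside the
angular range are refused rather than extrapolated. Builds derive one seed
per node from the build seed, so any slice can be reproduced standalone and
an interrupted build resumes from its checkpoint.

Desk-scale builds default to 1e6–1e7 photons per node rather than the
1e10-photon production scale a compute cluster would use; the table stores
per-photon values, so the scale affects per-node statistical noise, not
normalization.

## Geometry conventions

Room frame: right-handed, origin at the isocenter, +x patient-left, +y
patient-anterior (up for a supine patient), +z cranial. The PA pose places
the source under the table at `(0, -siso, 0)`; rotation order is frozen as
lateral about +z, then cranio-caudal about the rotated +x. These
conventions are documented rather than vendor-derived and may differ in
sign from a particular console. Source-to-isocenter distance defaults to
72 cm (typical isocentric C-arm); with the default torso — posterior
surface 12 cm below the isocenter — this reproduces a 60 cm
source-to-surface distance at PA with a 100 cm SID. Table motion is
modeled as a phantom translation, which is equivalent and keeps the C-arm
fixed in the room frame.

Voxel convention, stated once and used everywhere: 0-based indices, voxel
centers at `origin + (index + 0.5) * spacing`, millimeters internally,
dose in Gy.

## Phantoms and the synthetic torso

CT input is either a DICOM CT series or a raw-voxel container (int16 HU +
JSON sidecar). HU map to four materials (air / lung / soft tissue / bone at
-900 / -200 / 150 HU) and to density by a continuous piecewise-linear
calibration through (-1000, 0.0012), (0, 1.000) and (1000, 1.80) g/cm^3 —
a generic calibration, configurable because scanner curves differ. The
skin layer is the set of non-air voxels within `layerMm` (default 3 mm,
one voxel) of air by Euclidean distance, i.e. the air-adjacent shell at
the default.

The synthetic torso stands in for a body-phantom CT: an elliptical
soft-tissue cylinder (300 x 200 mm axes), two lung ellipsoids near -750
HU, a spine column near +700 HU, mild Gaussian HU texture (SD 15) inside
the body, centered 20 mm below the isocenter so the PA source-to-skin
distance is 60 cm. It emulates the gross attenuation contrast and the
closed skin surface of a torso; it does not emulate arms, bowel gas,
anatomical asymmetry, respiratory motion or positioning error — so
passing tests demonstrate correct transport and scoring on a realistic
attenuation structure, not anatomical fidelity for any patient.

## Acquisition pipeline

The synthetic console renders each fluoroscopic parameter as seven-segment
digits in fixed, non-overlapping ROIs described by a JSON-serializable
layout; a real, rectified camera frame could be described by the same
layout. Recognition is per-slot normalized cross-correlation against the
0–9/minus templates with acceptance threshold 0.6 and runner-up margin
0.05 — values chosen so clean frames are recognized exactly while
ambiguous slots are refused; both are exposed. A refused slot raises a
typed condition naming the failing field, so the stream layer re-emits the
last good record flagged stale (or a gap marker before any good record)
instead of guessing. Closest seven-segment glyph pairs (5/6, 8/9) correlate
near 0.82, far below the 0.95 acceptance-with-margin band, which is why
zero-noise recognition is exact.

Ultrasonic table ranging converts round-trip time of flight to distance
with the linear sound-speed model `v = 331.3 + 0.606 T` m/s — the standard
first-order temperature correction — halving for the round trip. Offsets
are measured distances minus per-axis calibration references, with a
per-sensor facing sign. The bench protocol (±10 cm sweep in 2 cm steps per
axis) is replayed in simulation and recovers every point exactly when
noiseless; a Gaussian ToF noise model exists for degradation studies only
and never enters acceptance checks, since measured hardware error is
specific to the sensors used.

## Session semantics

The orchestrator runs one skin-dose simulation per distinct
(conditions, pose, table offset) fingerprint and caches it; replaying the
same streams with the same seed reproduces every payload bit for bit,
because per-fingerprint seeds are derived from the session seed in
first-seen order. Dose accumulates as
`per-photon grid x calibration x mA x duration` per record, so cumulative
dose is monotone per voxel and invariant to stream chunking to 1e-12. The
cumulative display was chosen (peak skin dose is the injury-relevant
quantity); a `latestOnly` toggle shows only the current distribution.
During beam-off intervals payloads still carry the eye-lens rate computed
as if the latest conditions were active, flagged `predicted`, as a
pre-exposure risk cue. Colors are presentation only — a linear (optionally
log) ramp over [0, session max] — while dose values in Gy travel alongside
in the payload.

## Problem sizes in the tests

The suite exercises full-scale precision once — the 1e7-photon run on the
128 x 128 x 64 torso that checks the 3.5% peak-voxel criterion, about two
minutes of CPU — and uses 1e4–1e6 photons, 48^3-voxel phantoms and 3 x 3
angular tables everywhere else, where the properties under test
(conservation, symmetry, scaling laws, interpolation identities,
round-trips) are scale-free.

## Known limitations

* No secondary-electron transport; dose equals collision kerma.
* No tungsten characteristic lines; spectra are smooth Kramers models.
* The image receptor does not absorb the beam: past the patient the
  primary continues into the room, which overstates air scatter above the
  table in phantom-free comparisons (the suite probes patient-scatter
  dominance below table height, where backscatter dominates regardless).
* Collimator aperture shaping is not supported; fields are square.
* No deformable anatomy: the phantom is rigid; respiratory or patient
  motion is out of scope.
* One air-dose table per beam fingerprint; a deployment covering several
  protocols precomputes several tables.
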