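---
title: "Static musculoskeletal spine loading: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static musculoskeletal spine loading: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spineload)
```

`spineload` turns labeled vertebra segmentation volumes into
subject-specific static musculoskeletal models of the thoracolumbar spine
and computes the muscle forces and lumbar joint loads (compression,
anterior–posterior shear, lateral shear) needed to hold static postures.
This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic fixture does and does not show
about real data.

## Coordinate conventions

All geometry lives in world millimetres through the NIfTI affine
(0-based voxel indices).  The model frame is right-handed with +X
anterior, +Y superior, +Z subject-left; gravity acts along −Y at
9.81 m/s².  Moments about the anterior axis are frontal-plane (lateral
bending, `M_x`), about the lateral axis sagittal-plane
(flexion/extension, `M_z`); extension is positive about +Z, so imposed
flexion is a negative rotation about a joint's lateral axis.  Forces are
N, moments N·m (attachment coordinates are converted from mm
internally).

## Geometry extraction

Vertebra instance masks and subregion masks (vertebral body, arch,
spinous process, left/right transverse processes) are the input.  Before
any landmark is computed, the spine is realigned craniocaudally: the
rigid rotation that maps the T1–L5 centroid line onto the world vertical
removes the supine/upright posture difference.

Landmarks are geometric extreme values per subregion: the most
posterior/inferior/superior point of the spinous process, the most
lateral points of the transverse processes and (in the horizontal
midplane) of the vertebral body; vertebral-body rim points come from an
axis-aligned rectangle fitted to the sagittal midplane section whose
corner and edge-centre points are projected onto the body surface by
shortest distance; arch attachment points minimize the distance between
the arch's anterior border and the posterior body surface in the central
sagittal slab and in slabs shifted 10 mm left and right.  Ties in
extreme-value landmarks are broken toward the subregion centroid, which
keeps the extraction deterministic.

Two definitions the input data do not fix were resolved as follows:

* **Endplate centres and normals.**  A vertebral body is wider than
  tall, so its axis is estimated as the smallest-variance principal axis
  of the body voxel cloud (sign disambiguated by the centroid-spline
  tangent).  The endplate caps are the body voxels exposed along the
  grid vertical, restricted to a band near each end of the body and fit
  as thin disks (plane via principal components, with outlier trimming
  to reject staircase voxels from the tilted lateral wall).  Fitting the
  plane over the cap's full ~40 mm width averages voxel quantization
  down to sub-degree orientation error, which direct extreme-layer
  slicing cannot achieve on tilted vertebrae.
* **Joint frames.**  The joint centre is the midpoint between the
  superior endplate centre of the inferior vertebra and the inferior
  endplate centre of the superior vertebra.  Joint orientation comes
  from a natural cubic spline through the vertebral-body centroids,
  parameterized by cumulative chord length; the superior axis is the
  spline tangent where it crosses the inferior vertebra's superior
  endplate, the anterior axis is the tangent's in-sagittal-plane normal,
  and the lateral axis completes the right-handed triad.  Body centroids
  (not whole-instance centroids) drive the spline because the posterior
  processes bias instance centroids, and differently so for the sacrum
  block.

Alignment metrics are angles between endplate lines of the boundary
vertebrae: lumbar lordosis between the L1 and sacral superior endplates,
thoracic kyphosis between the T1 superior and T12 inferior endplates
(sagittal plane), and the frontal Cobb angle over the same thoracic
boundary pair.

## Tissue masses

Voxels are classified by configurable intensity windows (defaults: lung
[−1000, −500), fat [−200, −20), soft tissue [−20, 150) HU); bone voxels
from the instance mask are excluded.  Densities are 0.25 (lung), 0.96
(fat), 1.06 (soft) and 1.5 g/cm³ (bone).  Each classified voxel is
assigned to the vertebra nearest along the craniocaudal axis, which
yields contiguous axial slabs per level; the alternative reading of the
assignment rule (minimal anterior–posterior distance) produces
interleaved, anatomically implausible segments, so the craniocaudal
metric is used.  Head–neck and arm dummies are scaled from whole-body
mass inferred from the CT torso mass through a configurable
anthropometric fraction table (head+neck 8.1%, each arm 5.0%, trunk
49.7% of body mass); generic geometry scales linearly with stature.

## Passive elements

**Ligaments** (ALL, PLL, LF, ISL, SSL; one segment per system per
joint, T12/L1 through L5/S1) follow a piecewise force–length law per
parallel component: zero below the slack length `l_0 = (1 − eps_pre) ·
l_neut`, a power-law toe `K_nl (l − l_0)^exp_nll` up to `l_A`, then a
linear branch `F_A/n + K_lin (l − l_A)`.  Breakpoints are specified as
strains, so pre-loads are uniform across the segments of one structure,
with `l_neut` measured per segment in the neutral model.  The toe
coefficient and exponent are derived from the breakpoint data
(`exp_nll = eps_A / eps_lin`, `K_nl = (F_A/n) / (eps_A l_0)^exp_nll`),
which makes the law C1-continuous at `l_A` by construction; parameter
sets whose toe secant would exceed the linear stiffness (`exp_nll < 1`)
are rejected.  Shipped defaults: LF pre-strain 5% (reduced from the
often-cited 10%, which drives LF forces supra-physiological in flexion);
SSL pre-strain −10%, making it the only structure slack in neutral
standing.  Breakpoint strains and forces are representative of cadaveric
tensile data and ship as an editable JSON with a provenance note —
they are calibration inputs, not measured outputs.

**Discs** are lumped rotational elements: no moment inside a neutral
zone (default 1.5° sagittal/frontal), then a linear restoring moment
(defaults 1.8 and 2.2 N·m/°).  Viscous behaviour contributes nothing at
static equilibrium and is not represented.

## Muscle architecture

Nine groups, 103 point-to-point actuators: 49 per side plus five midline
interspinales.  Globally acting muscles (RA, EO, IO) and the
ribcage-attached parts of LL, IL and QL are one actuator per side;
lumbar fascicles of PM, QL, LL, IL and MF attach to named vertebral
landmarks.  The literature enumerates neither the exact merge that
yields 103 actuators nor every attachment, so the shipped table is a
reconstruction with these deliberate choices:

* **Thoracic multifidus** (three fascicles per side, PCSA fixed at
  1 cm²) descends from the T11/T12 spinous processes onto L1.  With the
  thoracic spine fused into one rigid body these are the only actuators
  spanning T12/L1 alone; without them the sagittal demand at T12/L1
  cannot be decoupled from the upper lumbar joints and heavy anterior
  holds become structurally infeasible at any muscle stress.
* **Psoas major** originates anterolaterally on the vertebral bodies and
  uses an anterior effective hip point — a straight-line surrogate for
  the muscle's path over the pelvic brim — so its weak upper-lumbar
  flexion arm survives the point-to-point simplification.
* **PCSAs** follow validated whole-trunk models rather than raw cadaver
  fascicle data; interspinales and thoracic multifidus get 1 cm².

Fascicles sharing a group, side and attachment subregions are merged by
summing PCSA.

## Statics and postures

Joint rotations are applied about each joint's own origin and axes and
propagate superiorly (chain kinematics); the sacral tilt acts as an
extra rotation at the lumbosacral pivot.  The net joint moment is the
moment of gravity and external loads on the superstructure about the
posed joint origin, plus ligament and disc contributions, negated —
i.e. what the muscles must generate.

* **Neutral standing** is found by minimizing the sum of squared
  sagittal net moments over the six joints (bounds ±10° per joint,
  L-BFGS-B from the zero posture with fixed settings, hence
  deterministic).
* **Trunk flexion** splits 40% into sacral rotation and 60% into lumbar
  flexion distributed 25.5 / 23.1 / 20.4 / 18.5 / 12.5% over L1/L2 …
  L5/S1; T12/L1 receives none.  The split is fixed for all flexion
  angles — a simplification of the real, angle-dependent lumbopelvic
  rhythm.
* **Load cases**: a held mass becomes a point load rigidly attached to
  the thorax at its anterior offset from a named reference (chest or
  sacral endplate); elevated arms move the arm-dummy centres of mass to
  shoulder height at a configurable anterior offset.  The neutral
  compensation is not re-optimized under load, so anterior holds
  overestimate demand exactly where a standing subject would lean back.

## Static optimization

Muscle forces minimize the sum of cubed muscle stresses
`sum_i (F_i / PCSA_i)^3` subject to frontal and sagittal moment
equality at the six joints (12 constraints; axial moments are left
free) and bounds `0 ≤ F_i ≤ sigma_max · PCSA_i`.  The maximal muscle
stress is first 0.6 MPa (60 N/cm²); a case that is infeasible there is
retried at 1 MPa.  In the default battery only "standing with 20 kg at
55 cm" needs the relaxed bound.

The cost is convex on the feasible box, so a deterministic
augmented-Lagrangian scheme (L-BFGS-B inner solves with analytic
gradients, multiplier updates and penalty growth outer loop) reaches the
global optimum; an optional fixed-seed multi-start exists purely as
verification.  The equality tolerance defaults to 0.1 N·m — two orders
below physiological moments.  True infeasibility (equality unreachable
within bounds) raises a classed error naming the worst joint
constraint.

Joint reactions sum gravity, external, muscle and ligament forces on the
superstructure, expressed in the joint frame: compression is the
negative superior component of the transmitted load, AP shear the
anterior component, lateral shear the lateral component.  Compression is
additionally reported normalized to the upright-standing value per
joint.  Ligament utilization is the force divided by the force at the
end of the linear region (`F/F_B`); values above 1 flag
supra-physiological loading.

## The synthetic spine

The generator builds T1–L5 plus a sacrum block from an elliptic-cylinder
body with box-shaped arch, spinous and transverse processes — the
simplest family exposing every subregion the landmark extractor needs.
Curvature is imposed by tilting each vertebra along circular arcs:
sagittal tilts span the lordosis angle over sacrum→L1 and the kyphosis
angle over T12→T1, frontal tilts span the Cobb angle over the thoracic
levels, so the requested angles are analytically recoverable from the
boundary endplates.  Default alignment is lordosis 29°, kyphosis 31°
(with an 18° frontal curve in the scoliotic preset) — a mildly curved
adult alignment; vertebrae are 22 mm high and 42 mm wide with 6 mm
discs, at 2 mm isotropic voxels (desk-scale volumes under 256³ with
landmark quantization at or below the voxel size).  The grid origin is
snapped to the voxel lattice so the sagittal midplane falls on voxel
centres and left/right structures rasterize as exact mirrors.  The
torso is an elliptical cylinder with two ellipsoidal lungs and a
subcutaneous fat shell whose cross-section fraction is the
`torso_fat_fraction` parameter; intensities sit at the centres of the
classifier windows, with optional Gaussian jitter that is off by
default because classifier tests need clean separability first.

What the fixture does not emulate: cortical/trabecular texture, CT
artifacts, realistic facet and process shapes, a shaped sacrum/pelvis,
or inter-subject anatomical variability.  Passing tests on it
demonstrate that the extraction, assembly and mechanics are internally
consistent and recover known ground truth — not that segmentation-level
noise or pathological anatomy are handled.

## Problem sizes and tolerances

The test suite and the acceptance script run the full 17-vertebra spine
at 2 mm voxels (≈ 6M voxel grids), the complete 10-case load battery,
1000-draw randomized property checks of the ligament law, and dense
1 N grid oracles for the toy optimization problems; the whole pipeline
completes in well under five minutes on one CPU.  Numerical tolerances:
3° for curvature round-trips (voxelization bound), 0.1 N·m for moment
equilibrium, 0.5% for mass conservation, 0.5%/1% for toy-problem
parameter recovery.

## Known limitations

Spherical joints with fixed centres of rotation (no facet joints, no
translation) concentrate flexion strain in the posterior ligaments —
the LF approaches its physiological limit near 30° flexion.
Intra-abdominal pressure is absent, inflating lifting loads.
Point-to-point muscle paths misestimate moment arms at large flexion.
The lumbopelvic rhythm is fixed.  Validation numbers tied to the
original in vivo comparisons require patient imaging data and are out of
scope here; the package's own checks are the configuration, property
and recovery suites above.
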