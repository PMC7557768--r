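---
title: "ppntract: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ppntract: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ppntract` implements a complete desk-scale pipeline for probabilistic
tractography of the pallidotegmental system — the connections between the
pedunculopontine nucleus (PPN) and the internal (GPi) and external (GPe)
globus pallidus — together with a synthetic phantom cohort generator that
provides full ground truth for every stage. This vignette documents the
model, the numerical choices, and the limits of the emulation.

# Tracking model

The tracker propagates streamlines over a *discrete-lobe orientation
field*: each voxel holds zero or more unit directions ("lobes") with
scalar amplitudes, stored in a compressed sparse layout
(`OrientationField`). This is a deliberate simplification of
spherical-harmonic fiber orientation distributions: it preserves the
sampling contract of FOD-based probabilistic tracking — amplitude-weighted
direction draws, an amplitude cutoff, curvature bounding — without
re-implementing spherical deconvolution, which is outside the package's
scope.

Parameters follow the common FOD parameterization:

- step size = `stepFactor` × voxel size (default 1.25, i.e. 1.5625 mm at
  1.25 mm voxels);
- maximum turning angle per step = `angleFactorDeg` × step / voxel size
  (default 30°, hence 37.5° for any isotropic voxel);
- amplitude cutoff 0.025; lobes below it cannot be drawn, and the
  phantom's background amplitude (0.01) therefore terminates propagation;
- bidirectional launching: one unconstrained initial draw serves as ±
  launch directions for two half-tracks that are concatenated through the
  seed vertex.

Each step samples a lobe by rejection (at most `maxTrials` draws) with
probability proportional to amplitude, restricted to the cone around the
previous direction, with antipodal sign resolved toward it. The update is
a circular-arc step of fixed arc length: for turning angle θ the chord is
2(step/θ)·sin(θ/2), taken along the bisector of the previous and sampled
tangents; θ = 0 reduces to a straight step. Single-direction-per-step arc
propagation approximates arc-path FOD samplers; it is probabilistic,
curvature-bounded and cutoff-terminated, but it is not a re-implementation
of any specific published integrator.

All randomness flows through R's RNG (the C++ inner loop draws via
`R::runif`), so a single `set.seed` makes tracking, phantom generation and
the whole pipeline reproducible.

# Phantom model

`phantomConfig()` defines a 40 × 48 × 32 grid at 1.25 mm — the package's
own choice of problem size, large enough for curved 30–40 mm bundles and
small enough that a 20-subject pipeline runs in ~2 minutes. World
coordinates are millimetres with the origin at the grid centre; all
geometry is mirror-symmetric about x = 0.

Per hemisphere the phantom places spherical ROIs for GPe (r = 3.75 mm),
GPi (3.125 mm), PPN (2.5 mm) and six exclusion nuclei (caudate, putamen,
accumbens, STN, SNc, SNr; 1.875 mm), plus a two-voxel midsagittal slab.
Each pallidal ROI is partitioned into three equal-count territory tiers
(limbic = anteroventral, associative = central, sensorimotor =
posterodorsal) along the axis (0, −1, 1).

Six pallidotegmental bundles (GPi-ipsi, GPe-ipsi, GPi-contra × L/R) and
four distractor bundles (terminating in exclusion nuclei) are defined as
smooth spline courses. Expected streamline counts are
`nTrueBase × multiplier`, with the effect knobs `gpiOverGpeRatio` (2.0),
`rightOverLeftRatio` (1.25) and contralateral factors (1.25 left, 0.875
right). Per subject, a rigid jitter (≤ 2 mm, ≤ 2°) maps template to
subject space; its inverse is stored as the known subject-to-template
transform. Ground-truth tractograms realize Poisson(`nTrue` × multiplier)
streamlines as control-point-jittered splines, resampled until the
pallidal end lies in the seed ROI and the far end in the target ROI.

## How tracked counts encode the planted effects

For the *tracked* (as opposed to ground-truth) pipeline, the orientation
field must make the planted count ordering emerge from geometry:

- outside the pallidal ROIs, each bundle contributes a tube of lobes
  (radius 2 voxels) whose directions point from the voxel centre to a
  centreline sample 6 voxels further along the course. This "funnel"
  keeps off-axis trajectories converging onto the tract while staying
  well inside the 37.5° turning cone (edge angle ≈ 18°);
- inside its seed ROI, a bundle's terminal field is a *coverage set* of
  `round(12 × multiplier)` ROI voxels nearest its planted endpoint,
  assigned disjointly across the bundles seeded in that ROI. Only
  coverage voxels carry lobes there, so the number of seed voxels the
  tracker can launch from scales linearly with the planted multiplier;
- planted endpoints sit on the ROI surface at the planted-territory pole
  (tilted ventrally), so the coverage cap hugs the ROI exit and the
  course leaves the ROI tangentially — a requirement discovered the hard
  way: interior endpoints strand streamlines in lobe-free ROI voxels, and
  course waypoints with hairpin turns are unfollowable at 37.5° per step.

Tracked NOS then recovers the planted *orderings* (GPi > GPe in both
hemispheres, right > left ipsilaterally, left > right contralaterally)
with high per-subject consistency; exact count *ratios* are not preserved
(selection losses differ per bundle), which mirrors how real
tractography reproduces orderings rather than absolute streamline
counts.

# Bundle selection

`selectBundle` keeps streamlines that touch the seed mask (with
bidirectional seeding the seed vertex is interior, so "touch", not
"start in", is the default), visit every include mask and avoid all
exclusion masks, tallying rejection causes. Mask visitation densifies the
polyline at half the smallest voxel edge, which prevents tunnelling
through one-voxel structures such as the midsagittal slab. The six
standard specifications are: ipsilateral — seed one pallidal segment,
include the ipsilateral PPN, exclude the other segment, the six
ipsilateral nuclei and the slab; contralateral — seed GPi, include the
contralateral PPN, exclude the six contralateral nuclei but *not* the
slab (the crossing is the point). No GPe-contralateral bundle is
reconstructed.

# Density maps, MPMs, topography and statistics

A track-density map counts *distinct* streamlines per voxel; the
voxel-visitation rule is the same densified-polyline contract used by
selection, and the test suite holds the implementation to an exhaustive
per-(streamline, voxel) oracle. Subject-level PPN-connectivity clusters
are computed in the fixed order: density → pallidal ROI masking →
25 % relative threshold → nearest-neighbour registration to the
template. Group maximum probability maps sum per-subject binary masks
and retain voxels covered by at least `ceiling(0.5 × N)` subjects.
Topography is quantified as percentage overlap, 100 × |A∩B| / |B|,
between the cluster MPM (A) and each territory MPM (B) — deliberately
asymmetric.

NOS comparisons use a hand-built paired two-sided Wilcoxon signed-rank
test (zero differences dropped, midranks for ties): exact by full
enumeration of sign assignments up to n = 12 (integer dynamic program
over doubled ranks), tie-corrected normal approximation with 0.5
continuity correction beyond. Seven fixed comparisons are run at an
uncorrected α = 0.05 (a Holm option exists but is off by default).

# Numerical choices

- Half-open voxel ownership: world point → voxel `floor(c + 0.5)` on the
  0-based index lattice, so boundaries belong to the upper voxel and
  ownership is unambiguous.
- Polyline densification: each segment is subdivided into
  `ceiling(length / h)` equal pieces with h = half the smallest voxel
  edge. This is the documented visitation contract; tests enforce it
  exactly rather than approximately.
- TCK offsets: the `file: . <offset>` header field participates in its
  own byte count; the writer fixes it by iterating the offset to a fixed
  point.
- NIfTI affines are written to both qform and sform (code 2) after
  setting pixdim, which round-trips grids through RNifti at ≤ 1e-5.
- Exact signed-rank enumeration uses counts over 2W (doubled midranks
  are integers), avoiding floating-point accumulation.

# Limitations

- Orientation fields are discrete lobe mixtures, not spherical-harmonic
  FODs; there is no crossing-fiber dispersion model beyond multiple
  lobes per voxel.
- Registration is rigid with known ground-truth transforms; nonlinear
  template registration is out of scope.
- The phantom's anatomy is schematic (spheres, spline tubes); it
  emulates the *logic* of pallidotegmental reconstruction — seed/include/
  exclude topology, crossing vs non-crossing bundles, territory
  topography, planted count asymmetries — not anatomical realism.
- Tracked NOS recovers orderings, not exact planted ratios (see above).
- DWI acquisition, preprocessing, response estimation and fODF fitting
  are entirely out of scope; the phantom supplies orientation fields
  directly.
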