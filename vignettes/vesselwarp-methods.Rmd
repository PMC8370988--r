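---
title: "Reconstruction and hemodynamics methods in vesselwarp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction and hemodynamics methods in vesselwarp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vesselwarp reconstructs femoropopliteal artery lumens by combining two
complementary imaging modalities. Biplane X-ray angiography sees the
artery's 3D course but, at ~0.2 mm detector pixels, cannot resolve the
intimal tears and false lumens that balloon angioplasty leaves behind.
Intravascular OCT resolves the lumen cross-section at ~10 µm but
acquires it as a straightened stack along the catheter pullback, with
no knowledge of the vessel's tortuosity. The package's central
operation maps the straightened OCT lumen onto the angiographic
centerline through a dense displacement field, producing an
anatomically correct, dissection-resolving surface model, and then
equips that model with physiological boundary conditions and
wall-shear-stress (WSS) post-processing.

This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic phantoms do and do not
establish about clinical data.

## Biplane centerline reconstruction

Each view is calibrated from radiopaque fiducials of known 3D position
by the direct linear transform: every correspondence contributes two
homogeneous equations in the 12 entries of the 3×4 projection matrix,
solved by SVD after Hartley normalization. At least 6 non-coplanar
markers are required; the bundled default layout uses 16. The
calibration residual is reported as reprojection RMS in pixels and,
with 0.5 px detection noise on 16 markers, sits in the 0.2–1.0 px
range.

The operator traces the left and right lumen edges in both views as
splines ordered proximal→distal. To triangulate them, points must be
corresponded across views. The package matches each sample of a
view-A edge with the point where the view-B edge crosses its epipolar
line, walking monotonically along the curve; normalized arc length
only breaks ties between multiple crossings and initializes the walk.
We adopted epipolar matching after finding that pure arc-length
correspondence — attractive for its simplicity — misplaces the
boundary by more than a millimetre on a 60 mm vessel bent at 50 mm
radius, because a foreshortened view parameterizes its silhouette
nonuniformly. Two degeneracies are handled explicitly: where the
epipolar plane leaves the other curve's extent (the last ~r of each
silhouette end) the correspondence is extrapolated linearly from its
matched neighbors, and the curve endpoints are pinned to each other
because the region of interest is delimited by operator landmarks
(catheter tip positions) visible in both views.

The centerline is the midpoint locus of the two triangulated boundary
curves — the inscribed-sphere alternative was rejected as needlessly
sensitive for the near-circular vessels this targets — regularized by
a smoothing spline per coordinate (`lambda = 1e-6` by default, which
keeps a straight phantom straight to well under 0.01 mm while
suppressing pixel-scale triangulation noise). Frames along the
centerline are rotation-minimizing (double-reflection transport)
rather than Frenet, because Frenet frames are undefined at the
inflection points of near-straight arteries.

On noise-free phantoms this chain recovers a straight axis to
~0.006 mm and a 50 mm bend radius to 0.01 %, with centerline Hausdorff
error below 0.1 mm — provided the views are chosen sensibly. A view
looking nearly down the vessel end is degenerate for silhouette
matching; the >45° separation rule (enforced as a warning) does not by
itself exclude such views.

## OCT lumen stack

Lumen contours (true lumen, and separate false-lumen contours inside
dissections) are rasterized per frame by even-odd scanline filling at
voxel centers on the native 0.0102 × 0.0102 × 0.2 mm grid. False
lumen is rasterized after true lumen and wins overlaps: dissection
membranes are thin, and false-lumen attribution drives the downstream
area statistics. Frames excluded by the operator (the clinical rule
excludes frames with more than one quadrant of the border invisible)
and unannotated frames (annotation every second frame, i.e. every
0.4 mm, is typical) are filled by per-label signed-distance
interpolation: the 2D signed Euclidean distance maps of the two
bracketing annotated slices are blended linearly and thresholded at
zero. This morphs shapes smoothly — two circles of radius 1 and 3 mm
interpolate to radius 2 at the midpoint — instead of duplicating the
nearer slice; a plain slice-copy mode is available
(`method = "copy"`). Gaps longer than `max_gap` (default 10 slices)
are refused. Labels are categorical, so resampling to the isotropic
0.075 mm working grid is nearest-neighbor.

## Warping the straightened lumen onto the centerline

The OCT-based centerline is the per-slice centroid of lumen voxels.
Its arc-length correspondence with the X-ray centerline is
piecewise-linear through landmark pairs (arterial side branches in
clinical practice); without landmarks, normalized arc length is used,
which assumes the ROI spans the same physical segment in both
modalities. Each slice is then given a rigid pose: translated to its
corresponding centerline point and rotated so its plane is orthogonal
to the centerline tangent. The in-plane orientation follows the
rotation-minimizing frames, with the whole family rolled by a
constant so that the proximal slice's pose is the minimal rotation
carrying the slice normal onto the proximal tangent (an arbitrary
frame seed would otherwise twist every slice rigidly, which both
distorts nothing physically and needlessly strains the numerical
inversion); an optional global `roll` supports landmark-based roll
registration.

The forward displacement field evaluates these poses at every voxel
of the straightened grid. Warping categorical labels requires the
*inverse* field on the target grid, computed by fixed-point iteration
`v ← v − α (v + u(y + v))` with under-relaxation `α = 0.5`,
tolerance 0.01 target voxels, and a 50-iteration cap. Two details
matter for robustness. First, the iteration is initialized by
scattering the forward-mapped voxel cloud into the target grid (mean
of `source − mapped` per occupied voxel, propagated into a 2-voxel
band); the naive start `v₀ = −u(y)` evaluates the field far outside
its source domain for strong bends and diverges. Second, plain
(undamped) iteration is only contractive while the slice rotations
stay small; the damped update converges whenever the forward map's
Jacobian eigenvalues have positive real part, which holds for all
bends the slice model itself permits. Bends tighter than five lumen
radii are rejected outright — the swept slabs would self-intersect.
Convergence and the reported composition residual
`max |u(y+v) + v|` are enforced on the warped-lumen voxels; the
surrounding interpolation band has no exact preimage by construction.
Target voxels then take the source label nearest to `y + v(y)`.

On a straight-to-arc warp (30 mm tube, 40 mm bend radius, 0.15 mm
voxels) the composition residual is ~0.01 voxel, labeled volume is
conserved to 0.03 %, per-slab cross-section areas to 2 %, and the
centerline round trip agrees with the target centerline to ~0.06 mm
over the interior. The end slabs are excluded from such comparisons:
a grid z-slice cuts a bent tube obliquely there, so its voxel
centroid is not a cross-section centroid. Two physical caveats are
worth keeping in mind when interpreting conservation numbers. The
bending map's volume Jacobian is `1 − x/R_b`: material on the inner
curve is genuinely compressed, so an asymmetric substructure such as
a one-sided dissection flap changes its volume *share* by roughly its
mean offset over the bend radius — a property of bending, not an
artifact. And the damped inversion converges only while the slice
rotations stay below ~60°; the optional global roll is meant for
small landmark-based corrections, and larger rolls should be applied
by rotating the source volume instead.

## Surface extraction and area accounting

The lumen surface is the zero level set of a scalar field built from
the labels: per-slice 2D signed distance (positive inside), combined
with the axial distance to the stack ends so the tube is capped, and
lightly Gaussian-smoothed (σ = 1 voxel in-plane plus a 1-2-1 axial
pass). The smoothing matters: the discrete distance transform is
quantized to boundary-pixel centers, and extracting the raw field
wrinkles the surface — on a cylinder this inflates area by ~10 % while
leaving volume unbiased. With smoothing, the extracted area is within
0.3 % at 0.12 mm voxels. The level-set shift the smoothing introduces
is O(σ²κ), micrometres at vessel scale. Extraction uses marching
tetrahedra on a uniform 6-tetrahedron cube decomposition (all sharing
the cube diagonal, so shared faces triangulate consistently): unlike
marching cubes it has no ambiguous sign cases, and the result is
watertight and consistently outward-oriented by construction. Faces
whose inward probe lands in false-lumen voxels are tagged
`false_lumen_wall`; at the corners where the false-lumen shells meet
the wall the assignment is ambiguous at voxel scale, which bounds the
false-lumen area accuracy at roughly 7–10 % for the phantom flaps.

Laplacian smoothing uses uniform weights (`v ← v + λ(mean(neighbors) −
v)`, default 20 iterations at λ = 0.5 — values chosen once as typical
mesh-processing practice; the upstream tooling this emulates does not
document its own). It reports the relative enclosed-volume change and
warns beyond 5 % shrinkage. Ends are clipped by planes orthogonal to
the centerline tangent at two stations, each open boundary loop is
extruded along the end tangent (default extension: three local
diameters, conventional CFD practice for moving boundary effects away
from the region of interest) and capped; caps are tagged
inlet (proximal) / outlet (distal). Area reporting follows the
clinical convention: wall totals in cm² (caps and extensions
excluded), inlet/outlet cross-sections in mm².

The solver export bundle writes the surface STL with a face-tag
sidecar and a configuration block carrying the volumetric-meshing
parameters (growth scale 1.8; boundary layer 6 × 0.15 mm), the blood
model (Newtonian, ρ = 1050 kg/m³, μ = 3.5·10⁻³ Pa s), the 2·10⁻³ s
time step and the 3-cycle/last-cycle analysis convention — these are
recorded verbatim for the external solver and never executed here.

## Boundary conditions

Inlet velocity waveforms are parameterized by duplex-ultrasound
extrema (PSV, MDV) per treatment stage and arterial segment; the
bundled population table covers pre-angioplasty, post-angioplasty and
post-stent stages. The triphasic template is a piecewise sinusoid —
forward systolic lobe (0.30 T), reverse lobe (0.20 T), small forward
late-diastolic lobe (0.25 T, amplitude 0.2 PSV), rest phase — scaled
so the extrema match exactly; the monophasic template is a single
lobe on a non-negative plateau. The phase fractions and the late-lobe
amplitude are template assumptions (configurable via
`phase_fractions`); the sources that define these waveform classes
publish shapes, not parameterizations. The cardiac period defaults to
1 s and is likewise a modeling choice. Net flow is verified positive
for every bundled parameter row.

The outlet is a two-element Windkessel, `C dP/dt = Q − P/R`,
integrated with an exponential midpoint scheme (exact for
piecewise-constant forcing) at the solver's 2·10⁻³ s step, cycle by
cycle from 80 mmHg until periodic; against the sinusoidal-forcing
closed form the amplitude is correct to <0.5 %. Calibration solves
the two-equation system {periodic max = 120, periodic min = 80 mmHg}
for (R, C) by damped Newton in log-parameters with finite-difference
Jacobian. It is a true inverse: parameter recovery is better than
0.1 %, and the calibrate→forward round trip reproduces 120/80 to
<0.1 mmHg. Constant flow leaves C unidentifiable and is refused. The
internal unit system is mm–s–MPa with explicit converters at every
interface (1 mmHg = 133.322387415 Pa).

## TAWSS and adverse-area reporting

TAWSS is the trapezoidal time average of per-face WSS magnitude over
one period. Classification uses strict inequalities — low < 0.5 Pa,
high > 7 Pa, boundary-equal faces are normal — and the area partition
is exact to floating tolerance. Low-TAWSS area on `false_lumen_wall`
faces is attributed separately, mirroring how dissection-related
adverse flow is reported clinically. Group summaries use sample SDs
and pooled-variance Student t-tests (Welch by flag); the pooled test
is implemented from the textbook formula so that identical groups
compare as t = 0, p = 1 rather than erroring, and is cross-checked
against `stats::t.test` on random data.

Where an external 3D solver is out of scope, the analytic Poiseuille
field supplies per-face WSS: `τ(t) = 4μ|Q(t)|/(π r³)` with the local
radius estimated per 2 mm arc-length bin from the main-lumen wall
area (`r = A/(2πw)`), and false-lumen faces attenuated by 0.05 —
a deliberately crude model of near-stagnant false-lumen flow whose
only claim is the *ordering* it induces: attenuated false-lumen faces
fall below the low threshold whenever the main lumen is below
10× the threshold. At the dissection margins the area-based radius
estimate dips where the flap corners meet the wall, which can push a
small band of faces past the high threshold — an artifact of the
stand-in field, not a hemodynamic prediction. Real per-face WSS
series from a solver can be supplied through `wss_series()` instead.

## Phantoms: what they establish and what they cannot

The phantom generator sweeps a tube along an analytic centerline
(straight / arc / helix / spline) with a radius profile, an optional
cosine-squared stenosis (severity = fractional radius reduction at
the throat), and an optional dissection: a circumferential shell flap
at uniform radial gap, the simplest geometry with a quantifiable
false-lumen area. Defaults are chosen at clinical scale: 2 mm lumen
radius, 0.3 mm flap thickness (a typical intimal flap, and ≥2 working
voxels so the flap survives voxelization), 75 mm pullbacks at 0.2 mm
frames, 0.0102 mm OCT pixels, 0.075 mm working voxels. Projections
are ideal pinhole (1000 mm source–target, 1200 mm source–detector,
0.2 mm pixels) with Gaussian detection noise; OCT contours get
Gaussian radial noise. Same seed, same phantom, bit for bit.

Phantoms validate the *operators*: calibration, triangulation,
correspondence, rasterization, interpolation, field inversion,
meshing, calibration of (R, C), TAWSS accounting. They do not emulate
OCT speckle, guidewire shadowing, cardiac-motion artifacts,
eccentric or multi-channel dissections, operator tracing variability
beyond isotropic noise, X-ray distortion, or vessel straightening by
the catheter — so passing tests demonstrate correctness of the
machinery, not clinical-grade robustness of segmentation inputs.

## Problem sizes and reproducibility

The test-suite and acceptance runs use 10–60 mm phantoms at
0.12–0.2 mm working voxels (10–30 voxels across the lumen) — sizes at
which every reported tolerance above was measured — while package
defaults keep the clinical 0.075 mm working resolution. All
randomness flows from explicit seeds; pipeline runs write a
provenance JSON recording the seed, the full configuration, and every
assumed default.
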