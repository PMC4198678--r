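---
title: "otodrill: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{otodrill: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otodrill)
```

# The problem

Training mastoid and skull-base drilling on cadaveric temporal bones is
expensive and access-limited, so voxel-based haptic simulators are used
as adjuncts: the trainee's stylus drives a virtual burr, the bone is a
labeled voxel model derived from CT imaging of a real specimen
("isomorphic": the virtual bone is the same bone the trainee could hold),
and the system must render both a smooth surface and stable contact
forces while material is removed in real time.  `otodrill` implements
that computational core as a headless, deterministic, fully testable R
package.  Everything an interactive trainer would do per millisecond
tick — proxy update, force law, carving, surface invalidation — is here,
minus the device drivers and the renderer, so every behavioural claim
can be asserted in a test.

# The model

## Labeled volume and materials

A model is a pair of grids on one lattice: an HU-like density (used for
iso-surfacing and segmentation) and an integer anatomic label (0 =
air/void).  *Collision and drilling use labels only* (`label != 0` is
"occupied"); density is retained for rendering-grade surfacing.  Voxel
`(i, j, k)` (0-based) has its centre at `origin + (i,j,k) * spacing`,
everything in millimetres.  Per-label material rows carry RGBA colour,
transparency, contact stiffness `k` (N/mm), a `drillable` flag, a
removal-ease multiplier (> 0), a removal resistance `R` (exposure
units), and a render flag.  `R` lives in the material table as an
explicit column because the removal law below needs a per-tissue
threshold; the source system describes modifiable ease but not its
mechanism, so the accumulator below is this package's documented choice.

## Model building

Bone is segmented by a closed HU window (`threshold_segment`); voxels
below the window stay void, which is what preserves the mastoid air-cell
system inside the bone instead of flooding it.  The HU window itself is
exposed as configuration (default examples use 500–3000) since the
source protocol does not state one.  High-resolution scans are reduced
in-plane by block means over `f x f x 1` blocks, with block-majority
labels (ties to the lowest id) and trailing voxels cropped with a
warning; block-mean is the variance-minimising linear reduction and
keeps total density mass exactly (a tested invariant).  Structure
meshes are voxelized by a centre-in-mesh parity test and painted onto
the volume in list order, later entries overwriting earlier ones (soft
tissue after bone), with voxels claimed out of void space given a
configurable representative density (default 1000) so they are
surfaced.

## Surfacing

`marching_cubes` is the standard 256-case cell lookup with linear edge
interpolation.  The case table is *generated, not transcribed*: for each
corner-sign configuration the contour segments on each face follow from
the face's corner signs, ambiguous (checkerboard) faces are resolved by
one fixed rule — cut off the above-iso corners — applied identically on
both sides of every shared face, segments chain into loops, and loops
are fanned from a root chosen so no fan diagonal lies inside a cube
face.  Three consequences, all tested:

* crack-free: adjacent cells always agree on shared-face segments;
* consistently oriented: faces are walked counter-clockwise as seen
  from outside the cube, so normals point away from material;
* 2-manifold: interior fan diagonals are private to their cell.

No asymptotic decider is applied, so on ambiguous configurations the
chosen topology may differ from the true field's — the classic marching
cubes limitation, acceptable here because collision uses voxels and the
surface is visualization/measurement.  Two numerical tie-breaks matter:
a corner exactly at iso counts as *outside* (`> iso` is inside), and
interpolation parameters are clamped to `[1e-6, 1 - 1e-6]` so an
exact-iso corner cannot collapse triangles to zero area and open the
mesh (displacement ≤ 0.5 µm at 0.5 mm spacing; relative volume effect
~1e-6).

The cell lattice is partitioned into 16³-cell chunks, each owning its
cells exclusively (no duplicated seam triangles).  A voxel edit marks
the chunks of every cell using that voxel as a corner; `update_dirty`
re-extracts only dirty chunks and the concatenation is
triangle-set-identical to a full recompute (the acceptance suite drives
500 random edits against the full-recompute oracle at 1e-12).  Chunk
recomputation is order-independent and side-effect-free — that is the
whole "multicore" contract, honoured here by construction rather than by
threads.

## Smoothing

Binary-occupancy surfaces are staircases.  `hc_smooth` runs the HC
variant of Laplacian smoothing: each iteration averages vertex
neighbours, then pushes vertices back along the correction
`b = p - (alpha * original + (1 - alpha) * previous)` by
`beta * b + (1 - beta) * neighbour-average(b)`.  Defaults `alpha = 0`,
`beta = 0.5`, 10 iterations follow the cited method's conventions (the
source system states none).  Smoothing is a global post-pass on the
assembled mesh, *not* per-chunk — local smoothing would make the result
depend on the chunk partition — and therefore the incremental-equality
guarantees apply to the unsmoothed mesh only.  Tests assert the
defining property (strictly less volume shrinkage than plain Laplacian
at equal iterations), dihedral-roughness reduction, exact connectivity
preservation, and the planar fixed point.

## Drilling

A spherical burr of radius `r` visits voxel centres within `r` of its
centre; drillable labels accrue exposure `rate * dt * ease(label)` and
are carved (density and label to 0) when exposure reaches `R(label)`.
`R = 0` (the default) reproduces instantaneous binary carving, which is
what the brute-force union-of-spheres oracle checks exactly; `R > 0`
yields the closed form `t = R / (rate * ease)`, so doubling ease halves
time-to-removal (tested at the exact boundary tick).  The voxel test
uses centres only — no partial volumes — to keep the oracle exact.
Undrillable labels are filtered before any state changes.  Motion
within a tick is sub-sampled at a quarter voxel so fast sweeps cannot
tunnel through thin plates.  One *stroke* is a maximal pedal-on
interval; its removals form one undo record, and undo is strictly LIFO,
restoring density, label and exposure bitwise.

## Haptics

The proxy ("position-locking" / god-object family) is a point
constrained to free space.  Each tick it marches from its previous
position toward the device in steps of a quarter of the smallest voxel
spacing; on striking an occupied voxel it stops at the last free
sample, estimates the outward normal by central differences of the
3³-box-smoothed occupancy (fallback: direction from the nearest
occupied voxel centre), projects the residual motion onto the tangent
plane and re-marches, at most three slides per tick.  Force is
`k(contact label) * (proxy - device)`, clamped to a configurable device
limit (3.3 N default — a typical entry-level stylus clamp, not a
measured value).  The original system's exact locking mathematics are
in its authors' separate reference and are not public; this
march-and-slide interpretation is chosen because it exhibits every
property attributed to position locking, and those properties are what
the tests pin down: non-penetration every tick, entry-side retention
three thicknesses deep into a two-voxel wall, no force-sign reversal
against the entry normal, and stable traversal of a three-voxel
channel.  The classical virtual-spring baseline
(`k * depth` toward the nearest free space from the *device*) is
implemented alongside purely to demonstrate its pop-through failure on
the same wall.

One shared stiffness per label drives both rendering and force (the
source does not distinguish them).  The haptic tick is 1 ms simulated
time; determinism is preferred over wall-clock fidelity throughout.

## Sessions and training modes

Sessions are JSON Lines — one header, one object per tick — with all
floating point at 17 significant digits, so parse(serialize(x)) is
bit-exact.  The header carries MD5 content hashes of the starting
volume and material table; passive replay refuses to run against
anything but the matching (isomorphic) model and then reproduces the
final volume and force trace bit-identically, because the whole engine
is deterministic.  Active-mode guidance matches the trainee pose to the
expert trajectory by nearest point *constrained non-decreasing* (the
source describes on-screen arrows but no matching rule; monotonic
matching with a 50-tick look-ahead is this package's choice, and the
monotonicity is a tested invariant so cues can never direct the trainee
backwards along the expert path).

# The phantom generator

No imaging from the source study is deposited, so the package generates
temporal-bone-like volumes with analytic ground truth.  The stated
world (defaults chosen once, on anatomy-scale reasoning, and not
revisited): 64³ voxels at 0.5 mm (a 3.2 cm specimen; 128³ is the
showcase size), an ellipsoidal cortical shell 2 mm thick at 1900 HU
around 700 HU trabecular bone, 40 air cells of 0.5–1.2 mm radius placed
by seeded dart-throwing with overlap rejection (so per-cell voxel
counts add exactly), one curved vessel-analogue tube, a one-voxel dural
plate analogue, and two ossicle-like ellipsoids; soft structures
default to undrillable.  Geometry fixtures (sphere, torus, slab,
channel) carry exact occupancy counts and analytic volumes.

The sphere/torus phantoms emit *partial-volume* boundary densities
(`clamp(0.5 + signed_distance / spacing, 0, 1) * HU`), as a CT of a
smooth object would; surfacing that field at half the material density
recovers geometry with sub-voxel accuracy (the 20 mm sphere's mesh
volume lands within 0.05 % of `4/3 * pi * r^3`, comfortably inside the
1 % acceptance band; the binary-occupancy surface of the same phantom
is within ~0.2 %).  The label grid stays the exact centre-in-sphere
digitization so voxel-level oracles remain exact.

What a green test does *not* establish: phantoms are geometric
idealizations — no anatomical realism, no CT noise or beam hardening,
no trabecular texture — so passing says the *engine* is correct on
volumes with known answers, not that drilling it feels like bone.

# Numerical choices and degenerate inputs

* Mesh voxelization casts +x rays per voxel-centre row; rays are offset
  by ~1e-6 voxel in y/z because voxel-derived meshes have edges lying
  exactly on lattice lines, which would graze the strict sign tests.
  Only points within ~1e-6 voxel of a surface can be affected, and the
  independent winding-number oracle in the tests samples exact centres.
* NIfTI-1 headers store spacing/origin as float32 by format definition;
  bit-exact geometry round-trips therefore hold for float32-representable
  values (payloads are float64/int32 and always bit-exact).  NRRD and
  raw+JSON print geometry at 17 significant digits and round-trip any
  double.
* NRRD/NIfTI are single-channel formats; labeled volumes write a
  `-labels` companion file, read back automatically.  The raw+JSON
  sidecar holds both arrays.
* A YAML dialect for material tables / phantom specs was dropped (no
  YAML parser in the supported dependency set); JSON serves both.
* Isolated mesh vertices never move under smoothing; empty meshes,
  empty edit sets, empty sessions and out-of-grid drill centres are all
  well-defined no-ops.
* An iso value outside the field's range yields an empty mesh, not an
  error (useful when scripting sweeps).

# Known limitations

* No asymptotic decider: ambiguous marching cubes cases take the fixed
  resolution; fine tunnels/handles at the single-cell scale may get the
  alternative topology.
* The proxy is a point; burr geometry affects carving but not contact
  (no 6-DOF torque rendering).
* No thermal, irrigation, bone-dust or acoustic/vibrational effects —
  the last of these the source itself reports as a deficiency of the
  original system.
* Real-time scheduling is out of scope; "real-time-style" means the
  incremental update path does strictly less work than a full recompute
  and is provably equivalent, not that frame deadlines are enforced.
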