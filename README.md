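# otodrill

**otodrill** is a headless R engine for voxel-based haptic simulation of
temporal-bone (mastoid) drilling — the computational core of a surgical
trainer, without graphics hardware, haptic devices or an operating
theatre attached.  It is written for simulation researchers and surgical
educators who need a *testable* implementation of the standard
drill-trainer stack:

* **Isomorphic model building** — turn segmented volumetric imaging
  (microCT-scale NRRD / NIfTI-1 / raw+JSON) and per-structure watertight
  meshes (PLY / STL / OBJ) into one labeled voxel model: HU-window bone
  segmentation that preserves mastoid air cells as voids, in-plane
  block-mean downsampling, parity-test mesh voxelization, and
  priority-ordered structure recombination with a per-tissue material
  table (colour, transparency, stiffness, drillability, removal ease).
* **Real-time-style surfacing** — chunked Marching Cubes (256-case
  lookup, linear edge interpolation, crack-free by construction) with
  dirty-region incremental updates that are provably identical to a full
  recompute, followed by Laplacian **HC** smoothing, which removes
  step-like voxellation artifacts while shrinking enclosed volume far
  less than plain Laplacian averaging.
* **Drilling** — a spherical burr carves drillable voxels under an
  exposure-vs-resistance accumulator (`t = R / (rate * ease)`;
  resistance 0 reproduces instantaneous carving), with undrillable
  anatomy protection and stroke-level LIFO undo (one stroke = one
  pedal-on interval) that restores the volume bitwise.
* **Position-locking haptics** — a proxy ("god-object") marches toward
  the device in quarter-voxel steps, locks onto surfaces, and slides in
  the tangent plane; force is `k * (proxy − device)`, clamped.  A
  classical virtual-spring (penalty) baseline is included to demonstrate
  the thin-wall pop-through failure that position locking avoids.
* **Training modes** — deterministic session recording (JSON Lines),
  bit-exact passive replay guarded by model content hashes ("replay the
  expert on *this* bone"), and active-mode guidance cues from monotonic
  nearest-point matching against the expert trajectory.
* **Phantoms** — since no public microCT accompanies the source study,
  a generator produces temporal-bone-like volumes with analytic ground
  truth: ellipsoidal cortical shell, trabecular interior, seeded
  non-overlapping air cells, vessel/nerve tubes, a dural-plate slab and
  ossicle-like ellipsoids, plus sphere / torus / thin-wall / channel
  fixtures for verification.

## Worked example

```r
library(otodrill)

ph <- make_phantom(phantom_spec(seed = 1))   # 64^3 voxels at 0.5 mm
ph$volume
#> <labeled_volume 64x64x64, spacing 0.5x0.5x0.5 mm, 94416 occupied voxels, labels {1,2,3,5,6}>
ph$truth$air_cell_voxels                     # exact void ground truth
#> [1] 968

mesh <- hc_smooth(marching_cubes(ph$volume))
c(closed = mesh_is_closed(mesh), euler = mesh_euler(mesh))
#> closed  euler
#>      1     82
```

Euler characteristic 82 = 2 x 41 closed components: the outer bone
surface plus the walls of the 40 preserved air-cell voids — the
honeycomb is modelled as void space, not filled in.

```r
# descend onto the bone: probe with the pedal off, then carve
c0 <- (ph$volume$dims - 1) / 2 * ph$volume$spacing
poses <- cbind(c0[1], c0[2], c0[3] + 15 - (1:300) * 0.05)
pedal <- c(rep(FALSE, 150), rep(TRUE, 150))
res <- simulate_trajectory(ph$volume, ph$materials, drill_bit(1.6),
                           poses, pedal, seed = 1)
sum(ph$volume$label != 0) - sum(res$volume$label != 0)
#> [1] 628                                   # voxels carved
max(sqrt(rowSums(res$trace[1:150, c("fx","fy","fz")]^2)))
#> [1] 3.3                                   # probe phase: clamped at 3.3 N
table(res$trace$contact[res$trace$contact > 0])
#>   1   2   5
#> 132   3 100                               # ticks touching cortical bone,
                                            # trabecular bone, dural plate
```

With the pedal off the position-locking proxy rests on the surface
while the device is pushed ~5 mm deep, so the spring force saturates at
the 3.3 N device clamp; with the pedal on, the 1.6 mm burr carves along
the proxy path (the carved set is checked against a brute-force
union-of-spheres oracle in the test suite) and the proxy follows the
receding surface down through cortical bone onto the dural-plate
analogue — which is undrillable and survives.

A command-line pipeline wraps the same calls
(`inst/cli/otodrill --help`): `phantom`, `build-model`, `simulate`,
`replay`, `extract-surface`, `report`; all subcommands are
deterministic under `--deterministic`.

## Acceptance

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The source study reports survey statistics and hardware facts rather
than recomputable numbers, so there are no numeric acceptance targets
(`{}` is emitted); the engine's acceptance battery is property-based and
runs inside the test suite (`tests/testthat/test-acceptance.R`):
incremental-surface oracle equivalence after 500 seeded edits, 1 %
geometric accuracy on a 20-mm sphere phantom with correct sphere/torus
topology, the HC anti-shrink property, carving-oracle exactness with
undrillable protection and mass conservation, bit-exact undo/replay,
thin-wall and constrained-channel haptic stability versus the
virtual-spring baseline, guidance monotonicity, and CLI determinism.

See the methods vignette (`vignettes/otodrill-methods.Rmd`) for the
model, its assumptions, parameter defaults and known limitations.
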