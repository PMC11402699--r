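---
title: "Methods: image-based finite element estimation of plate bending loads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based finite element estimation of plate bending loads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When a fractured proximal phalanx is stabilized with a plate, rehabilitation
exercises (full fingertip-to-palm flexion) impose internal loads on the
osteosynthesis that had not been quantified. `platebend` implements a
desk-scale version of the combined experimental--computational workflow that
determines those loads: CT-like volumes of the instrumented finger are turned
into specimen-specific finite element (FE) models; optically tracked fragment
motions, expressed at reference divots machined into the plate, drive the
model; and the internal bending moment is read off at a cut plane through the
plate's mid-section that follows the deformed centerline. A synthetic phantom
generator supplies every input with known ground truth, so each stage is
testable without any scan data.

# Pipeline stages and their models

## Synthetic phantom (`make_phalanx_phantom`)

The phantom is an idealized hollow cylinder: cortical tube (default outer
radius 3.2 mm, wall 1.2 mm, length 30 mm) along *x*, marrow inside,
soft-tissue background outside, with a transverse osteotomy gap (default
3 mm) centred at mid-length. HU defaults (cortex 1500, marrow 150,
background 0, additive Gaussian noise SD 25 HU) keep the cortex alone inside
the standard 400--4000 HU segmentation band. Voxels are classified by their
centre (partial-volume-free), and the grid is aligned so the fracture plane
is a voxel boundary; at 0.5 mm voxels the 3 mm gap is exactly six empty
planes. The default radii were fixed once, on geometric grounds: at the
default 0.25 mm voxel they make the voxel-centre count of the cortical
annulus representative of its analytic volume to about 1% (some radius/voxel
combinations sit on unlucky lattice resonances with errors of several
percent). The phantom deliberately omits trabecular structure, cortical
porosity, beam hardening and anatomical curvature: it is a geometry with
closed-form volume and known fragment masks, which is what the oracle tests
need. Passing tests therefore demonstrate correctness of the *machinery*, not
realism of phalangeal anatomy.

## Imaging (`segment_bone`, `register_rigid_nmi`, `crop_to_osteotomy`)

Segmentation thresholds inclusively at 400--4000 HU, then applies a
morphological closing (ball radius 2 voxels) and fills enclosed cavities.
The cavity fill is three-dimensional (background components not connected to
the volume border). A per-slice 2-D fill was considered and rejected: on
transverse slices of a tubular bone it floods the marrow cavity, which would
break the property that the segmented mask matches the cortical annulus.

Registration maximizes normalized mutual information,
NMI = (H(A)+H(B))/H(A,B), over the 6 rigid DOFs with a Nelder--Mead simplex
(gradient-free), coarse-to-fine over a 2-level image pyramid, 32 histogram
bins, rotations parameterized about the fixed-image centre. The result is
never allowed to be worse than the initial transform, and an overlap below
10% raises a flag. Rigid-only: no scaling or deformable component.

Cropping removes the slab of voxels within half a gap width of the fracture
plane and partitions the rest by the sign of the projection onto the gap
normal. On the phantom this reproduces the generator's ground-truth fragment
masks voxel for voxel.

## Density and modulus (`map_density`, `density_to_modulus`)

HU map to bone mineral density linearly and density maps to modulus by a
power law E = c (rho/rho_ref)^p. The scanner calibration and the constants
of the published density--modulus law are not part of this artifact's
sources, so the defaults (identity HU-to-density; c = 10 GPa at
rho_ref = 1000 mg HA/cm^3, p = 1.5) are explicit configuration, flagged as
such, with a modulus floor (0.01 MPa) so empty elements cannot make the
stiffness singular.

## Meshing (`voxels_to_tet10`, `make_plate`)

Fragment masks are coarsened to cubes of the target edge (an integer
multiple of the voxel size); a cube is kept when at least half its voxels
are in the mask, and each cube splits into six straight-sided quadratic
tetrahedra along the Kuhn triangulation (consistent diagonals, never
inverted; the tetrahedralization partitions the cubes exactly, so mesh
volume equals block volume to machine precision). Two numerical choices
matter and are deliberate:

* **Grid alignment.** The coarsening grid is aligned so the osteotomy faces
  are block boundaries (`align_point`). Without this, half-cut blocks
  rebuild bone inside the gap at coarse edges -- a 1.0 mm grid turned the
  3 mm gap into an effective 2 mm gap and inflated the mid-plate moment by
  roughly the ratio of the spans.
* **Block-mean density.** The element modulus comes from the mean density
  over the whole parent block (zero outside the mask), so partial-volume
  blocks get proportionally lower stiffness. Using the mean over masked
  voxels only would over-stiffen coarse staircase walls.

The plate is meshed the same way on a box grid (default edge 0.25 mm, the
resolution a convergence study supports; the pipeline's default solve uses
0.5 mm and the convergence criterion below guards the difference). Cubes
whose footprint is at least half inside a screw hole (25-point subsample)
are removed; hole-boundary node sets and the two divot points are labelled.
The plate's CAD dimensions are not published, so the default
24 x 4 x 1.5 mm with 1.5 mm holes at (-10, -5, +5, +10) mm follows the
printed hole layout (5 mm spacing, 5 mm from the fracture line) and is
configuration-driven.

## Screw ties (`apply_ties`)

Screws are not meshed. Each screw hole is coupled kinematically to the bone:
a linearized rigid motion (translation + small rotation) is least-squares
fitted to the weighted displacements of the bone-surface patch within the
search radius (default 2 mm, spanning the screw length) of the hole's anchor
point, with quadratic-taper weights 1-(d/R)^2, and every hole-boundary node
follows that fitted motion evaluated at its own position. This choice is the
result of a measured failure: the simpler nearest-node master--slave tie has
mesh-dependent point-coupling compliance and changed the mid-plate moment by
over 100% between 1.0 and 0.5 mm bone meshes; patch-average interpolation
still evaluated the fragment motion at the patch centroid and left ~20%.
The rigid-fit coupling is exact for a rigidly moving fragment at any
discretization, and the measured convergence of the reference model is ~1%.
A slave node coincident with a bone surface node is tied to it directly, so
coincident-interface assemblies reproduce the merged mesh exactly (this is
one of the FE oracles).

## Solver (`assemble`, `solve_step`, `solve_steps`)

Standard isoparametric tet10 linear elasticity: 4-point Gauss rule (exact
for straight-sided elements), Voigt order (xx, yy, zz, xy, yz, xz) with
engineering shear. Elements congruent up to translation share one
unit-modulus stiffness matrix (a cube-split mesh has six classes), scaled by
the element modulus at assembly. The tied system is reduced by the coupling
projection and solved by sparse supernodal Cholesky; the factorization is
reused across the ten load steps.

Boundary conditions follow the experiment's logic: the proximal fragment's
end-cap nodes are fixed, and the distal fragment's end-cap nodes are
displaced rigidly by the measured relative transform applied about the
distal divot, in `n` evenly spaced steps. Step interpolation is geodesic
(constant axis, linearly scaled angle; linear matrix interpolation leaves
SO(3)). The default solver is linear small-strain; an incremental mode
(update coordinates, re-assemble per step) approximates geometric
nonlinearity and is intended for small models -- congruence caching does not
apply to deformed meshes. Plasticity is carried in the calibrated material
model but not integrated: at single-digit N mm moments the plate stresses
stay far below the 100.3 MPa yield, and a warning is emitted if any plate
element's von Mises stress crosses it. Plate--bone and bone--bone contact
default to off (a 3 mm gap does not close under rehabilitation-scale
motion); an optional node-to-plane penalty contact (stiffness 100x the
maximum diagonal) guards gap-closure studies.

## Kinematics (`fit_rigid_transform`, `relative_transform_at_divot`)

Marker clouds are reduced to rigid transforms by the SVD (Kabsch) fit with a
reflection guard; collinear marker sets are rejected because rotation about
the line is unobservable. The relative transform is T_prox^{-1} o T_dist,
re-expressed with the distal divot as the rotation reference point -- the
divot is the measured landmark, so the FE drive and the measurement refer to
the same point. Only the final pose is interpolated into steps; the full
trajectory is not replayed.

## Section resultants (`moment_curve`, `cut_plane_resultants`)

The plate centerline is built from slab centroids of plate nodes displaced
by the FE field; the cut plane at the mid-station is normal to the
centerline tangent, i.e. it transforms with the deformation. Resultants use
the free-body cut: elastic nodal forces of the elements on one side, summed
over the nodes shared with the other side, give the action of the distal
side on the proximal side (the fixed sign convention); computing from the
other side flips the sign exactly, which is asserted to 1e-6. The reported
bending moment is the norm of the two transverse components; torsion about
the tangent is excluded. Because the deformed lever arms make the moment
quadratically nonlinear in the load, the exact-linearity checks use the
`deformed = FALSE` variant, which evaluates the same resultants in the
reference configuration (the strict small-strain convention); the default
remains the deformation-following plane.

The flexural capacity comparison uses the rectangular-section formula
allowable = sigma_f b h^2 / 6: a moldable composite patch of 6 x 3 mm at
69 MPa flexural strength allows 621 N mm, two orders of magnitude above the
single-digit N mm demand.

## Study design and statistics (`run_pipeline`, `summarize_moments`)

The synthetic design mimics the study layout: specimens x digits x repeats
(defaults 2 x 2 x 3). Specimen-level jitter perturbs phantom radius
(SD 0.15 mm) and cortical HU (SD 60); digit/repeat-level jitter perturbs the
imposed motion (SD 0.2 deg about a 2 deg flexion-scale rotation with a
0.1 mm transverse translation). These scales are choices, made once, to give
the ANOVA stage real group structure at desk scale; they do not emulate any
measured inter-specimen variance. Summaries report mean and sample SD (n-1)
per specimen, per digit and overall, and one-way ANOVA F and p across each
grouping via the standard linear-model decomposition; a design in which all
values are identical leaves F undefined and is flagged rather than computed.
Runs are deterministic under the master seed (every noise source derives its
seed from it), and the summary CSVs are byte-reproducible.

# Problem sizes and defaults

The reference model (phantom at 0.25 mm voxels, bone mesh 1.0 mm, plate mesh
0.5 mm) has roughly 18k nodes / 10k quadratic tetrahedra and solves ten
steps in seconds; the refined bone mesh (0.5 mm) has ~60k nodes. The mesh
convergence criterion -- at most 5% change in the maximum bending moment
between those two resolutions -- is the same parameter-of-interest criterion
the meshing stage is built around, and measures ~1% here. The default
pipeline keeps these sizes; they are the package's chosen desk-scale
operating point, stated here so users know what the defaults buy.

# Known limitations

* Elastic-only solver (plasticity carried, not integrated); incremental
  geometric update is an approximation, not a finite-strain formulation.
* The density--modulus constants are placeholders by necessity; absolute
  bone stiffness is therefore configuration, though the plate-dominated
  bending moment is insensitive to it.
* The phantom's idealized geometry means the absolute moments are not
  comparable to cadaver-specific values; only scales, trends and invariants
  are.
* Registration is rigid-only and local (simplex from the initial guess);
  it is not a global aligner.
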