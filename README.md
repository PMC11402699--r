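# platebend

Internal bending loads on phalangeal fracture-fixation plates, computed
from image-based finite element models driven by measured fragment
kinematics.

## The problem

After a proximal phalanx fracture is plated, early rehabilitation
(fingertip-to-palm flexion) loads the osteosynthesis — but how much?
Knowing the internal bending moment at the plate is what lets a new
fixation concept (such as a moldable composite patch built over the
screws) be judged against the actual mechanical demand rather than
against another implant. `platebend` implements the computational half of
a combined experimental–computational workflow at desk scale:

1. **Synthetic specimen** — a CT-like phantom of an osteotomized phalanx
   (hollow cortical cylinder, 3 mm mid-diaphyseal gap, configurable HU
   and voxel size) with ground-truth fragment masks, plus a de-featured
   four-hole plate, optical-marker trajectories, and PEEK dog-bone
   tension curves. Every downstream stage is testable against this
   generator's known truth.
2. **Imaging** — threshold segmentation in the 400–4000 HU band with
   closing and cavity fill, rigid co-registration by normalized mutual
   information, NMI = (H(A)+H(B))/H(A,B), and cropping of the registered
   intact mask to the osteotomy pattern, yielding artifact-free fragment
   masks with per-voxel density.
3. **Kinematics** — SVD (Kabsch) rigid fits of marker clouds, the
   relative fragment transform T<sub>prox</sub>⁻¹ ∘ T<sub>dist</sub>
   re-expressed at the plate's distal reference divot, and geodesic
   interpolation into 10 evenly spaced displacement steps.
4. **Material** — PEEK constants calibrated from dog-bone curves: elastic
   window least squares for E, lateral-strain slope for ν, 0.2%-offset
   yield, and the post-yield (plastic strain, stress) table.
5. **FE model** — quadratic tetrahedra (tet10) from a Kuhn split of
   density-mapped voxel blocks (E = c·(ρ/ρ₀)^p per element), the plate
   meshed the same way, screw holes coupled kinematically to the bone
   surface, proximal end fixed, distal end driven by the measured
   transform; sparse Cholesky solves per step.
6. **Section loads** — free-body cut at the plate mid-length on a plane
   that stays normal to the deformed centerline; the bending moment is
   the norm of the two transverse moment components, and its maximum over
   the steps is the headline quantity. A flexural capacity check
   (allowable = σ_f·b·h²/6) compares the demand against a rectangular
   composite patch section.

A pipeline driver runs specimens × digits × repeats with seeded jitter,
writes per-run moment curves, summary tables, and provenance, and reports
means ± SD with one-way ANOVA across specimens and digits.

## Worked example

```r
library(platebend)

# PEEK calibration from a synthetic dog-bone curve
curve <- make_dogbone_curve()        # generator truth: E 1740.5, nu 0.3779
fit_material_model(curve)
#> material_model: E = 1740.5 MPa, nu = 0.3779, yield = 100.3 MPa, 52 plastic points

# reference phantom -> FE model -> mid-plate bending moment
ref <- phantom_reference_moment(bone_edge = 1.0)
round(ref$moment, 2)
#> [1] 8.12
tail(as.data.frame(ref$curve)[, c("step", "N", "M_t1", "M_t2", "M_bend")], 3)
#>    step        N     M_t1          M_t2   M_bend
#> 8     8 12.44948 6.517360 -0.0002697823 6.517360
#> 9     9 13.74455 7.321489 -0.0002823059 7.321489
#> 10   10 14.98129 8.123262 -0.0002901082 8.123262

# capacity of a 6 x 3 mm moldable patch at 69 MPa flexural strength
capacity_check(ref$moment, width = 6, thickness = 3, flexural_strength = 69)
#> capacity_report: demand 8.12 N mm vs allowable 621 N mm -> safety factor 76.4
```

The ten steps ramp the imposed motion evenly, so the moment curve rises
monotonically to its maximum at full flexion; `N` is the axial force
through the section and `M_t1` the flexion-plane bending component.

The reference model imposes a flexion-scale relative fragment motion
(2° about the plate width axis at the distal divot plus 0.1 mm
transverse translation) and yields a maximum mid-plate bending moment of
about 8 N·mm — the single-digit N·mm regime that makes a patch with a
hundreds-of-N·mm allowable moment a comfortable fixation. Refining the
bone mesh from 1.0 mm to 0.5 mm changes the moment by about 1%, inside
the 5% mesh-convergence criterion the meshing stage is designed around.

The full synthetic study:

```r
summ <- run_pipeline(pipeline_config(seed = 1), out_dir = "out")
print(summ)   # mean +/- SD over runs, ANOVA by specimen and digit
```

## Scope notes

The solver is linear small-strain elastic (an incremental
geometry-update mode approximates geometric nonlinearity); plasticity is
calibrated and carried but not integrated, with a yield-exceedance
warning. The density–modulus constants are explicit configuration. See
`vignettes/platebend-methods.Rmd` for the models, numerical choices and
limitations.
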