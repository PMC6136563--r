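---
title: "Modelling canine retraction: stress, movement, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling canine retraction: stress, movement, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthofem)
```

## The problem

During orthodontic canine retraction, a spring tied between the canine
bracket and a temporary skeletal anchorage device (TAD) applies a
continuous force of about 100 gf (modelled here as exactly 1 N) that pulls
the tooth distally into an extraction space. The tooth moves because the
stress carried by the periodontal ligament (PDL) drives alveolar bone
remodelling. `orthofem` implements the full desk-scale analysis chain for
this situation:

1. a parametric stand-in for the segmented patient anatomy (tooth, PDL,
   alveolar bone block, bracket and TAD points, and the root landmarks
   C1D, C2D, C1M),
2. a region-tagged tetrahedral mesher,
3. a small-strain linear-elastic finite-element solver that recovers a
   stress invariant at the three landmarks under the 1 N retraction load,
4. a quadratic *calibration law* that maps landmark stress X (N/mm²) at
   the start of a month to the clinical movement Y (mm) observed over that
   month,

   Y = a X² + b X + c,  with calibrated values a = 2960, b = −254.56,
   c = 5.667,

5. validation machinery (rigid best-fit superimposition, landmark
   displacement, Dahlberg method error, difference/percent summaries)
   mirroring how serial dental casts are compared in the clinic.

The calibration coefficients were obtained on one patient (12 landmark ×
month points) and validated by predicting a second patient's monthly
movement from that patient's own computed stresses; both printed tables
ship with the package (`load_calibration_table()`,
`load_validation_table()`).

```{r law}
law <- calibrated_movement_law()
predict_movement(law, c(0.030, 0.048, 0.063))
reproduce_paper()
```

## Geometry: what the synthetic anatomy emulates

No CT or scan data are available, so `build_model()` generates a
parametric segment in a fixed convention: x mesial(−)/distal(+),
y buccal(+)/palatal(−), z apical(−)/coronal(+), origin at the cervical
centre of the canine. The root is a tapered cone with elliptical
cross-section (mesio-distal semi-axis 2.8 mm at the cervix, 0.8 mm at the
apex, bucco-palatal 0.85× those), which is the simplest shape that keeps
a distinct distal and mesial surface for the C1D/C2D/C1M landmarks; the
crown is a capped frustum. The PDL is a uniform 0.25 mm shell — a typical
physiological thickness; none of the patient dimensions are published, so
all of these are free parameters of `anatomy_config()`, not
reproductions of anyone's anatomy. The bone block (18 × 12 × 18 mm) has a
1.5 mm cortical shell on its outer faces and around the crest, and
cancellous bone inside. Landmarks sit exactly at 1/3 and 2/3 of root
length on the distal surface and 1/3 on the mesial surface.

`random_seed` only jitters the exported surface triangulations by ±0.1 µm
(emulating scan roughness); the macro-geometry and the volume mesh are
fully deterministic.

What the generator does *not* emulate: real root curvature and cross-
sectional irregularity, the lateral incisor/second premolar and archwire
(their mechanical role is minor for the canine-root stress under a
point-specified load), gingiva, and any patient-specific socket shape.
Consequently, passing tests demonstrate the correctness of the machinery
and the plausibility of magnitudes, not agreement with any particular
patient.

## Meshing

`tetrahedralize()` uses a boundary-fitted ring template centred on the
tooth axis: concentric rings (tooth interior, root surface, PDL layers,
graded bone rings out to the block boundary, with the four block-corner
directions included exactly) are extruded through z-levels snapped to the
cervix, apex and PDL apex cap. The triangular prisms are split into
tetrahedra along each quad face's diagonal through its minimum global
node index — a rule that is consistent between neighbours and provably
never produces the undecomposable (Schönhardt) diagonal cycle, so the
mesh is conforming by construction. Elements are tagged
tooth/pdl/cortical/cancellous by analytic classification of their
centroids; the tooth/PDL and PDL/bone interfaces coincide with element
faces along the root, and only the small apex cap is tagged
approximately. Defaults: `target_edge = 0.7` mm and two element layers
through the PDL thickness (~41,000 tet4 elements), chosen because a
single layer through a nearly-incompressible 0.25 mm shell locks
severely (see below). `order = 2` produces 10-node tetrahedra by edge
midpoint insertion.

## The elastic model

All tissues are isotropic linear elastic (E in N/mm², ν dimensionless):
cortical bone 13,800/0.26, cancellous bone 345/0.31, tooth 20,000/0.15,
PDL 0.68/0.49, stainless steel 210,000/0.30. The 100 gf clinical force is
modelled as exactly 1.0 N, applied at the mesh node closest to the
bracket point, directed at the TAD. The bracket–archwire "touch contact"
is simplified: by default there is no wire (pure point load); a
`wire_axis` option imposes a sliding multi-point constraint that removes
bracket displacement perpendicular to the wire. The bone block is fixed
on its mesial, distal and deep cut faces (the original model's maxilla
fixation is not described anywhere, so this is a package choice). One
elastic solve represents one monthly snapshot; no viscoelasticity, large
deformation, contact or remodelling mechanics is included, and root
resorption is out of scope.

The solver assembles the standard B-matrix/D-matrix stiffness (exact for
tet4, 4-point Gauss for tet10), eliminates constraints by a
transformation matrix, and factorizes the reduced SPD system with sparse
Cholesky (relative residual checked against 1e-8). Verification battery:
patch test to machine precision, uniaxial bar σ = F/A within 1%, slender
tet10 cantilever within 5% of PL³/3EI, reaction equilibrium below
1e-8 N, exact linearity in the load, and frame invariance of landmark
samples under a common rotation.

## Stress sampling and its interpretation

The landmark stress is, by default, the von Mises invariant of the
volume-weighted average stress tensor over PDL elements whose centroids
lie within twice the local edge length of the landmark
(`von_mises_at()`, with `measure = "max_principal"` as the alternative).
Neither the invariant nor the tissue is stated in the source analysis;
this choice is explicit and configurable.

Two consequences of this choice are worth understanding:

* **Magnitude.** A thin ν = 0.49 PDL under near-normal loading carries an
  almost purely hydrostatic stress state; von Mises sees only the
  deviatoric part, roughly (1−2ν)/(1−ν) ≈ 4% of the normal traction.
  With the defaults the landmark von Mises values are ≈ 0.003–0.006 MPa,
  below the 0.028–0.063 MPa calibration range, while the compression-side
  mean hydrostatic magnitude (~0.02–0.03 MPa at C1D) does fall in that
  range. The package therefore logs the [0.01, 0.10] MPa plausibility
  envelope as a soft pass/warn status rather than asserting it; with the
  shipped defaults the status is *warn*, which we report as-is.

* **Convergence.** Displacement-based tet4 elements lock volumetrically
  at ν = 0.49. Measured landmark von Mises over the refinement sequence
  `target_edge` = 1.0, 0.7, 0.5, 0.35 mm (two PDL layers) changes by
  13–29%, 5–9% and 4–8% between successive meshes: convergence is
  monotone but slow, and a full edge-halving from the default still moves
  two of the three landmarks by 10–18%. The shipped convergence test
  asserts the <10% band between the default and a 1.4×-refined mesh;
  the tet10 option is the practical remedy when tighter convergence is
  required.

## Movement prediction and the multi-period study

`run_study()` loops: mesh → solve → sample stress at the period start →
predict the month's movement with the law → advance the geometry →
re-mesh. Stress at Tᵢ predicts movement over Tᵢ→Tᵢ₊₁, following the
calibration table's row structure. Since three scalar landmark movements
under-determine a 6-DOF motion, `advance_geometry()` builds displacement
targets along the distal load direction (projected into the
mesio-distal/occlusal plane) and recovers the best-fit rigid motion by
Kabsch superimposition, reporting the fit residual; the tooth, PDL and
socket move while the block boundary stays fixed (clinically, the socket
follows the tooth through remodelling, which is also why serial models
superimpose rigidly). Each period re-tetrahedralizes the advanced model —
the simplest correctness-preserving choice; how the original monthly
models redistributed PDL geometry is not described, so this is a package
decision. The per-period "clinical" movement of the synthetic study is
measured with the same superimposition + landmark-displacement machinery
used for real casts, with the bone block as the stable reference.

Because the default synthetic stresses sit below the calibrated range,
the law (whose minimum, ≈0.19 mm at X ≈ 0.043, lies inside the
calibration interval and which rises toward its intercept c = 5.667 mm
as X → 0) predicts several mm per month there — a reminder that the
calibration is only valid over 0.028–0.063 N/mm². The prediction is
always positive (the discriminant of the calibrated quadratic is
negative), so cumulative movement grows monotonically.

Rounding follows the tables: internal arithmetic is unrounded; display
rounding is half-away-from-zero to 3 dp (mm) and 2 dp (percent). The
percent denominator is the unrounded prediction F: this reproduces both
printed extremes (0.36 and 8.96) exactly and all individual percent
cells within ±0.06 points — the residual cell-level discrepancies
(e.g. 7.59 vs 7.61) cannot be resolved by any simple rounding
convention, so per-cell checks use that ±0.06 band while range checks
are exact at 2 dp.

Whether the calibrated coefficients came from a least-squares fit of all
12 calibration points is not decidable: an OLS quadratic on the
packaged table gives visibly different coefficients (the calibration
data contain a documented measurement issue in the first patient's C1M
series). `reproduce_paper()` therefore reports the refit *next to* the
calibrated law without asserting equality, and `fit_movement_law()`
exposes `exclude = "C1M"`.

## Numerical choices and degenerate inputs

* Quadratic fits use QR (`stats::lm`); the tests cross-check against an
  independent dense normal-equations solve. Fewer than three distinct
  stresses raises a rank-deficiency error.
* Kabsch superimposition rejects collinear point sets; the proper
  rotation is enforced by the determinant sign correction.
* Degenerate (zero-volume) tetrahedra are flagged by `mesh_quality()`;
  the mesher itself orients all elements positively and is deterministic.
* Binary STL stores float32, so round-trip fidelity is ~1e-6 mm only for
  coordinates below 16 mm; ASCII export (9 significant digits) covers
  the full block.
* Problem sizes: the default study meshes ~41k tet4 elements per period
  (~13k nodes); the verification battery uses boxes of a few hundred to
  a few thousand elements. A `--paper-scale` density (~100k elements) is
  reachable by setting `target_edge ≈ 0.45` but is not the default.

## Known limitations

Linear elasticity with a homogeneous PDL is the weakest link: real PDL
response is nonlinear and time-dependent, and the quadratic law bakes
both tissue response and remodelling into three coefficients valid only
inside the calibrated stress window. The synthetic anatomy supports
correctness claims, not patient-specific prediction. Two patients'
printed tables cannot support statistical inference beyond the RMSE and
residuals reported by the fit.
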