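---
title: "Methods: a synthetic finite-element study of residual discoid meniscus volume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a synthetic finite-element study of residual discoid meniscus volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the study design

A discoid lateral meniscus (DLM) is a congenital variant in which the
lateral meniscus forms a near-complete disc covering the lateral tibial
plateau. Symptomatic discoid menisci are treated by saucerization — partial
meniscectomy that removes central tissue and preserves a peripheral rim. The
clinical question this package addresses computationally is how much tissue,
and which part of it, must be preserved: how do tibiofemoral shear and
compressive stresses change as a function of the residual meniscus volume
and of its anterior/posterior distribution?

The study design is a single static stance load case solved over a family of
15 meniscus models. The discoid meniscus is divided into five concentric
zones by volume ratio — 15/15/15/15 % from the inner free margin outward,
with a 40 % peripheral rim — and split into anterior and posterior halves of
equal volume. Residual models remove whole zone-halves innermost-first,
independently per half, with residual fractions drawn from
{100, 85, 70, 55, 40} % and an anterior-posterior difference of at most 30
points; the rim is never removed. Models are named `NNaMMp` by their
anterior/posterior residual percentages (`85a70p` keeps 85 % of the anterior
and 70 % of the posterior half). Three comparisons are reported: the
equal-ratio series (100 to 40 %), five equal-total-volume pairs with
mirrored anterior/posterior distribution, and step series holding one half
fixed while the other is reduced.

Because no patient geometry is available, the joint itself is a parametric
synthetic stand-in. Absolute stresses from such a geometry are not
comparable with any patient; the object of study is the *relative* response
of the stress readouts to the resection family, which is why the package's
checks are oracle verification of the numerical core plus the qualitative,
within-study comparisons above.

## Synthetic joint geometry

`knee_config()` / `build_knee_geometry()` construct an idealized
tibiofemoral joint at full extension in a fixed frame (x medial to lateral,
y posterior to anterior, z up; origin at the tibial plateau centroid; units
mm, MPa, N):

* **Tibial side.** Two elliptic cartilage plates (default semi-axes 15 x 17
  mm, thickness 2 mm) with flat superior surfaces at z = 2, on a rigid
  tibia-fibula body that is fully fixed.
* **Femoral side.** Each condyle's articulating surface is a bi-radius
  paraboloid (frontal radius 24 mm, sagittal 32 mm) — the shallow-contact
  approximation of a bi-spherical condyle. The cartilage solid sits between
  this surface and the rigid bone above it.
* **Discoid lateral meniscus.** A wedge disc whose inferior surface lies on
  the tibial plate and whose superior surface conforms to the femoral
  cartilage over the whole disc, with thickness 2 mm under the condyle apex
  growing to about 7 mm at the outer margin. It covers 95 % of the plateau
  area (`discoid_coverage`); coverage 1 gives a solid disc. The default
  peripheral height (7 mm) is chosen so that the conforming regime extends
  to the outer margin for the default condyle curvature: a discoid meniscus
  is thick and molded to the condyle, and a thinner wedge would leave the
  rim out of contact and unload exactly the models (rim-only residuals) the
  study cares about.
* **Medial meniscus.** The C-shaped meniscus is idealized as an annulus with
  inner rim ratio 0.55; the open-horn gap of a real C is not modelled. The
  ratio -> 0 limit reproduces the solid-disc construction exactly, which
  pins the two builders against each other in tests.
* **Ligaments.** Cruciates as small bundles of Neo-Hookean fibers,
  collaterals and the patellar/quadriceps path as linear fibers, all
  tension-only, anchored on the bone surfaces (the patella is not a body;
  its tendon path ends at a fixed virtual point). Under the single axial
  load case they are secondary stabilizers.

Two deliberate geometric decisions carry the science:

1. **Exact anterior-posterior symmetry of the articulating surfaces and
   menisci.** The equal-volume anterior/posterior split and the
   equal-volume resection pairs (`85a70p` vs `70a85p`) are only meaningful
   if mirrored resections really have equal volumes. Every surface is
   symmetric about y = 0, the angular grid count is even, and the
   tetrahedralization of the posterior half mirrors the anterior pattern,
   so mirrored models solve on mirror-identical meshes and their volumes
   agree to machine precision.
2. **Anterior-dominant contact via a cartilage thickness gradient.** In the
   extended knee, tibiofemoral contact concentrates anteriorly; this is
   what makes anterior tissue more valuable than posterior tissue. Shifting
   the condyle anteriorly would encode this but breaks property 1 (the
   conforming meniscus would inherit the asymmetry, and pair volumes would
   differ by more than the bookkeeping tolerance). Instead the femoral
   cartilage carries a linear anterior-posterior thickness gradient
   (`cartilage_ap_gradient = 0.35`): thinner, hence stiffer in compression,
   anteriorly. On the intact joint this yields an anterior contact-force
   share of about 52 % on the lateral meniscus — a deliberately moderate
   bias whose direction, not magnitude, drives the pair comparisons, since
   the mirrored meshes remove all discretization noise from those
   comparisons.

What the generator does *not* emulate: patient-specific surface detail,
meniscal horns and root geometry, cartilage thickness maps, the patellar
compartment, flexed poses, and any population variability. Passing tests on
this geometry show that the pipeline reproduces the *mechanistic* response
of an idealized discoid knee to volume-ratio resection; they do not certify
patient-level stress magnitudes.

## Materials

Material cards (`default_materials()`) are, in MPa: rigid bones; isotropic
cartilage E = 15, nu = 0.3; transversely isotropic meniscus with
circumferential modulus 140, radial = axial modulus 20, in-plane Poisson
ratio 0.2, out-of-plane 0.3; Neo-Hookean cruciate fibers (ACL C1 = 5.08,
D1 = 0.00683 1/MPa; PCL C1 = 6.06, D1 = 0.0041); linear collateral and
patellar/quadriceps fibers with E = 60, nu = 0.3.

The transversely isotropic card needs two constants the moduli above do not
determine: the in-plane shear modulus is fixed by isotropy of the
radial-axial plane, G = E_plane / (2 (1 + nu_plane)) = 8.33 MPa, and the
out-of-plane (fiber) shear modulus defaults to 57.7 MPa, a value
conventional in meniscus finite-element work; both are configurable. The
circumferential direction is the stiff axis, realized per element as the
tangent of the level-set contour of distance to the outer margin (azimuthal
for a circular disc), with the axial direction global z.

The cruciates are fiber bundles, not continua: uniaxial incompressible
Neo-Hookean stress sigma = 2 C1 (lambda^2 - 1/lambda), nominal force
sigma A / lambda, tension-only; the small-strain modulus is 6 C1. The full
compressible energy W = C1 (I1bar - 3) + (J - 1)^2 / D1 is implemented at
the material-point level so both constitutive parameters stay live and
testable.

## Contact solver

`build_fe_model()` / `solve_static()` solve small-strain TET4 elasticity
with node-to-surface penalty contact:

* Boundary conditions follow the stated stance case: tibia-fibula fixed;
  femur rigid with exactly three free degrees of freedom — medial-lateral
  translation, axial translation, varus-valgus rotation (rotation about y);
  flexion, anterior-posterior translation and internal-external rotation
  fixed. The femoral cartilage bone-side surface is tied to the femur rigid
  body; the tibial cartilage base is fixed; each meniscus is anchored at its
  peripheral bottom margin, idealizing the meniscal root and capsular
  attachments to the tibia. A 1150 N vertical load acts at the femur
  reference point.
* Contact pairs are small-sliding: each follower node is paired once with
  its nearest target facet and keeps that pairing and normal. Pairs:
  meniscus superior surface against femoral cartilage, meniscus inferior
  surface against tibial cartilage, and femoral against tibial cartilage
  (the direct path through the resection defect), per compartment,
  frictionless. The per-area penalty stiffness is
  `penalty_factor * E_target / h` (default 50 x 15 / h MPa/mm); residual
  penetration beyond 0.02 mm triggers automatic x10 escalation (up to three
  times). Initial gaps are clamped at zero: chordal faceting of the curved
  target surfaces would otherwise report sub-element "penetration" of
  perfectly conforming interfaces and prestress the joint at zero load.
* With a fixed contact active set the system is linear, so the solver is an
  active-set Newton iteration: assemble the penalty terms for the current
  set, factorize (sparse Cholesky), solve, update the set; converged when
  the set is stable and the relative residual is below 1e-6. Because the
  problem is piecewise linear, a load ramp does not change the converged
  state (verified to 1e-10 mm against a 4-increment ramp), so the default is
  a single increment; `load_case(increments=)` restores a ramp. Everything
  is deterministic: fixed assembly ordering, no randomized preconditioning,
  bit-identical repeat runs.
* The three free femur degrees of freedom carry a weak grounding spring
  (1e-3 N/mm) so the stiffness is non-singular before contact engages; at
  equilibrium the spring force is nanonewtons and the global balance error
  (applied load vs tibial reaction) is ~1e-6 of the load, far inside the
  0.5 % bookkeeping bound.

Stress recovery is element-constant (material law applied to the element
strain, no nodal averaging), and the two readouts are the Tresca stress
(stress intensity, sigma1 - sigma3, twice the maximum shear stress) and the
minimum principal stress, whose magnitude is reported as compressive
stress. Principal values use the closed-form trigonometric eigensolution,
which lets a general eigensolver serve as an independent oracle in the
tests. Peaks are taken per compartment (MFC/LFC, MM/LM, MTC/LTC, with
cartilage split medial/lateral by centroid sign), deterministic with
lowest-element-id tie-breaks; empty compartments are recorded as absent.

## Resection pipeline numerics

Zone boundaries are inward offsets of the outer margin in the structured
radial parameter. For meniscus solids built by this package the partition
regenerates the structured mesh with the zone radii as grid surfaces,
iterating the radii (Newton on the level-set volume derivative) until each
whole-shell cumulative volume matches its target; realized fractions then
hit 15/15/15/15/40 % to ~1e-7 and no cut elements (hence no slivers) exist.
For foreign meshes a general conforming level-set cut is used instead
(marching-tetrahedron subdivision with shared edge cut points and
minimum-index face diagonals, watertight by construction), and the same
machinery positions the anterior/posterior plane by volume bisection; on
the package's own symmetric meshes that plane coincides with a mesh plane
and requires no cutting.

Junction smoothing for unequal anterior/posterior models is a constrained
radial relocation: the inner-wall radius follows a smoothstep ramp between
the two cut radii over a +/-3 mm band around the split plane, and whole
radial node columns rescale accordingly. This preserves element quality and
watertightness by construction, reduces the dihedral discontinuity across
the plane (about 1.64 rad for the raw step, 0.8-1.2 rad after smoothing at
the default mesh), and drifts the volume by well under the 1 % allowance.
An earlier surface-Laplacian smoother was rejected: vertex-only relaxation
distorts the adjacent elements and *amplifies* element-constant peak
stresses at the junction.

## Numerical choices and their reasons

* **Mesh resolution.** The default element edge length is 1.5 mm for
  cartilage and menisci (bones are rigid surfaces faceted at 2 mm). This
  was fixed by a convergence probe at 2.5, 2.0 and 1.5 mm: the coarse level
  smears the stress concentration on the narrow rim of the 40 % models
  (which carries the study's headline jump), and the middle level shows a
  discretization artifact in the pair orderings that both finer and coarser
  levels contradict; 1.5 mm is the coarsest level probed at which both the
  equal-ratio step ordering and the pair orderings are stable. A full
  15-model study at this resolution runs in roughly ten minutes on one CPU.
* **Tolerances.** Volume bookkeeping: zones within 0.5 percentage points
  (realized ~1e-7), halves within 0.5 %, residual totals within 1 % of
  (a + p)/2 before smoothing and 1.5 % after, conservation exact by
  construction. Solver: relative residual 1e-6, penetration cap 0.02 mm.
* **Degenerate inputs.** Configuration validation names the offending field;
  open meshes are rejected by the volume and partition routines with the
  achievable-range message when a target fraction cannot be bracketed;
  smoothing abandons (with a warning, returning the unsmoothed model) if it
  would invert elements or drift volume beyond 1 %.
* **Ties.** Peak extraction breaks ties by lowest element id; the
  level-set splitter snaps nodes within 1e-9 of the iso-value onto the cut
  to avoid degenerate slivers.

## Known limitations

* Absolute stress magnitudes are those of an idealized geometry; the
  literature comparison (`validate_against_literature()`) is a plausibility
  report with flags at [0.5 x min, 2 x max] of three published whole-joint
  peak tables, never a pass/fail gate. On the default study the meniscus
  and tibial-cartilage peaks sit below those spans — expected, since the
  conforming synthetic joint distributes load more evenly than a real one.
* The anterior-dominance signal is deliberately moderate (52 % anterior
  share). Its sign is robust on the mirrored meshes, but the magnitude of
  anterior/posterior pair differences is small (a few percent), and the
  compressive readout of the rim-only comparison (40a40p vs 40a55p)
  reverses — consistent with the source study's own report that the
  minimum-principal comparisons admit exceptions. The package asserts pair
  orderings on the Tresca readout and reports the compressive one.
* TET4 elements with element-constant stress are the stated discretization;
  peaks are mesh-dependent quantities and are only compared within a fixed
  mesh, never across resolutions.
* Single pose, single load, no friction, no poroelasticity, no dynamic
  effects; fibula merged with the tibia; no patellofemoral compartment.
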