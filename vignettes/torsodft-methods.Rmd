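---
title: "Simulating defibrillation fields and thresholds in synthetic torso phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating defibrillation fields and thresholds in synthetic torso phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

An implantable cardioverter-defibrillator (ICD) shock sets up a quasi-static
electric field between the shocking coil in the right ventricle and one or
more return electrodes (the pectoral can, optionally SVC or CS coils).  In
the resistive-volume-conductor approximation the extracellular potential
$V_e$ obeys the generalized Laplace equation

$$\nabla \cdot (\sigma \nabla V_e) = 0,$$

with homogeneous region conductivities $\sigma$ for the torso tissues, an
anisotropic conductivity tensor in the ventricular myocardium, Dirichlet
conditions on the electrode surfaces (shock coil at the applied voltage,
grounds at 0 V) and no-flux conditions on the torso boundary.  Defibrillation
success is predicted by the critical-mass criterion: a shock defibrillates
when at least 95% of the ventricular myocardial volume experiences a field
magnitude $\lVert \nabla V_e \rVert \ge 5$ V/cm.  Because the problem is
linear, a single solve at a 10 V test shock determines the defibrillation
threshold (DFT): if $g_{05}$ is the field level (V/cm) exceeded by 95% of
the myocardial volume at 10 V, then

$$\mathrm{DFT} = 10\,\mathrm{V} \times \frac{5}{g_{05}}, \qquad
  E_{\mathrm{DFT}} = \tfrac{1}{2} C\, \mathrm{DFT}^2, \; C = 100\,\mu\mathrm{F}.$$

Shock impedance is $R = V / I_{\mathrm{total}}$ with $I_{\mathrm{total}}$
the current leaving the shocking coil, and the mean E-field is the
volume-weighted mean of $\lVert \nabla V_e \rVert$ over the ventricular
myocardium at 10 V.

The package runs this model over a synthetic cohort of 20 torso phantoms
(5 anatomies x healthy/HCM/DCM/ICM variants) and 10 ICD configurations
(left/right can x apical/septal RV coil, with SVC/CS/SVC+CS ground-coil
augmentations of the right-sided-can setups), and compares configurations
with paired Wilcoxon signed-rank statistics, reported as median and IQR.

## The synthetic phantoms

The phantoms are analytic stand-ins for CT-derived torso models.  A torso is
an ordered list of labelled solids resolved by the painter's algorithm; the
regions are: inner body (bath), skin, bones, kidneys, liver, stomach, spleen,
lungs, LV/RV myocardial walls, left/right atrial walls, aortic and SVC
walls, blood pools, valves, and (ICM only) scar.  The heart is built from
truncated prolate-ellipsoid shells: the LV cavity has short semi-axis
LVEDD/2 and long semi-axis 1.6 x LVEDD/2 (a typical end-diastolic
length-to-diameter proportion), the wall is a concentric shell of the
nominal thickness, the base truncation sits at 35% of the cavity long
semi-axis, and the RV is a second shell (free wall 3.5 mm) offset towards
the right-anterior chest and carved against the LV so that the septum
belongs to the LV wall.  Atria are thin spherical shells (2 mm), the aorta
and SVC are 2 mm-walled tubes, and the abdominal organs are coarse
ellipsoids at fixed anatomically plausible offsets - only their conductivity
contrast matters to the field.  All lengths are in mm.

The five base anatomies carry the reference heart dimensions returned by
`cohort_heart_dimensions()` (LVEDD 42-54 mm, wall 11-13.5 mm) and
per-anatomy body-size scales of 0.93-1.05 about a compact adult torso
(chest half-axes 112 x 85 mm).  Both choices are fixed properties of the
generator, not tuning knobs: the heart dimensions are the study's reference
values and the size scales represent inter-subject variation
deterministically, so that a cohort is reproducible from its seed alone
(the seed only samples the ICM scar territories).

Remodelling follows the clinical definitions:

* **HCM** thickens the LV wall homogeneously *inward* into the blood pool
  to the target thickness (the measured cavity diameter shrinks
  accordingly; the epicardial contour is unchanged).
* **DCM** dilates the cavity radially to the target LVEDD at the equator,
  with a $C^1$-smooth attenuation profile that tapers the dilation to zero
  at the apex and at the base plane; wall thickness is preserved.
* **ICM** inserts a spheroidal transmural scar patch (default radius
  25 mm) into the LV wall at an angular position set by the coronary
  territory: LAD anterior, LCx lateral, RCA inferior.  Scars replace only
  points labelled LV wall, so a scar can never leak into the cavity or the
  torso.  Scar conductivity is an assumption (see below): real
  infarct-scar conductivity is poorly constrained and the source data used
  MRI-derived scar geometries that this parametric generator does not
  reproduce.

What the generator deliberately does **not** emulate: CT image noise and
segmentation error, trabeculation and papillary muscles, pericardium,
vessel tortuosity, true statistical shape variation, and image-derived scar
morphology.  Tests passing on these phantoms therefore validate the solver
and the metric definitions and the *relative* ranking of electrode
configurations under controlled geometry; they do not certify absolute DFT
magnitudes for real patients, which depend on torso size and anatomical
detail.

## Electrodes

Hardware dimensions are fixed: RV and SVC coils 2 mm diameter x 8 cm, CS
coil 2 mm x 4 cm, can 6 cm diameter x 1.3 cm placed subcutaneously below
the clavicle and tilted to the local chest-wall normal.  The RV lead
follows one course per heart - down the RV cavity to the apex, with the
excess lead bowing inside the right atrium.  The *apical* position puts
the coil tip at the apex end of this course; the *septal* position is the
same lead pulled back so that the tip sits at 50% of the apex-to-base arc.
(A first implementation built the septal coil as a separate line hugging
the septum 3 mm off the LV epicardium; that places the shock source
*closer* to the LV than the apical lead, which inverts the physics of a
pulled-back lead and is not how a septal position arises clinically.  An
8 cm coil also cannot be "centred" at mid-septum of a ~5 cm apex-to-base
extent.)  Electrodes absent from a configuration are absent from the
model; their volume keeps the conductivity of the surrounding tissue.

## Discretization

Phantoms are voxelized on a uniform cubic lattice: every cell whose
centroid carries a non-air label is split into the six Kuhn tetrahedra
sharing the cell diagonal (a conforming decomposition), and the element
label is the label at the cell centroid.  The default desk-scale spacing
is `h = 2.5` mm (about 2.7 M tetrahedra per torso); the oracle problems in
the test-suite run at `h = 1.25` mm.

**Electrode-surface snapping.**  Stair-stepped voxel electrodes carry an
$O(h)$ bias of the effective electrode size; for mm-scale coils at desk
resolution that bias reaches ~10% in impedance, which is unacceptable.
Lattice nodes within 0.45 h of an analytic electrode surface are therefore
projected onto that surface before the Dirichlet sets are formed, restoring
second-order geometric accuracy (on the concentric-sphere benchmark at
h = a/4 this reduces the impedance error from ~11% to ~1%).  A repair pass
halves the displacement of any node whose tetrahedra would degenerate
(volume below 2% of the lattice tet volume); snapped meshes therefore
deviate from the exact lattice volume only by $O(h^2)$ near electrode
surfaces, and `tetrahedralize(..., snap_electrodes = FALSE)` recovers the
exact lattice decomposition.

**Fibres.**  Myocardial fibre vectors follow a rule-based transmural helix:
the helix angle interpolates linearly from +60 deg at the endocardium to
-60 deg at the epicardium (configurable), with the fibre laid in the local
tangent plane of the shell.  Transmural depth comes from the analytic shell
coordinate for phantom meshes and from a Laplace-Dirichlet solve
(endocardium 0, epicardium 1) for imported meshes.  Where no usable depth
exists the fibre falls back to circumferential with a warning.

**Conductivities.**  Isotropic region values (S/m): bath 0.24725, skin
0.117, bones 0.05, kidneys/liver 0.1667, stomach/spleen 0.1, lungs 0.0714,
atrial walls 0.25, blood pools and valves 0.6667.  The myocardial tensor is
$\sigma_t I + (\sigma_l - \sigma_t) f f^T$ for unit fibre $f$.  The
intra/extracellular pairs ($\sigma_{il}=0.174$, $\sigma_{el}=0.625$,
$\sigma_{it}=0.019$, $\sigma_{et}=0.236$ S/m) must be combined into one
static tensor; the default is the **bulk (monodomain-equivalent) sum**
$\sigma_l = 0.799$, $\sigma_t = 0.255$ S/m, with an extracellular-only mode
(0.625/0.236) available via `conductivity_map(myocardium_mode =
"extracellular")` - the combination rule is a genuine modelling choice, not
a derived fact.  Three further values are assumptions flagged here: aortic
and SVC wall conductivity (0.25 S/m, the atrial-wall value), and scar
conductivity (0.05 S/m, isotropic, bone-like - scars are low-conductivity
but no measured value is available; both are `conductivity_map()`
arguments).

## Solver

P1 finite elements yield a symmetric positive definite system (assembled in
compiled code; conductivities are converted to S/mm so that currents come
out in A).  Dirichlet constraints are imposed by symmetric reduction.  Two
solution paths exist:

* **direct** (CHOLMOD sparse Cholesky) for meshes below ~150k nodes or
  without lattice metadata;
* **multigrid-preconditioned conjugate gradients** for lattice meshes: a
  geometric hierarchy coarsens every second lattice node per dimension,
  prolongation is trilinear interpolation renormalized over existing
  nodes, coarse operators are Galerkin products $P^T K P$, smoothing is a
  symmetric Gauss-Seidel V(1,1) cycle, and the masked coarsest system is
  solved directly.  Electrode masks are restricted through the levels with
  a neighbourhood rule so thin coils stay represented on coarse grids.
  Convergence is declared at relative residual $10^{-8}$ (configurable);
  typical cohort solves need ~20 PCG iterations.

Within one model the stiffness matrix and hierarchy are assembled once;
each configuration enters as the Dirichlet mask plus a local sparse
correction for the snapped nodes, and the previous configuration's
potential warm-starts the iteration.

**Electrode currents.**  Two extraction rules are implemented.  The default
is the discrete nodal reaction: $I_e = \sum_{i \in e} (K u)_i$, the
standard conservative FEM flux (the sum over all electrodes vanishes to
solver tolerance; on the slab it is exact and on the concentric-sphere
benchmark it is within ~1% of the closed form).  The surface-triangle rule
- electrode surface area x surrounding conductivity x mean of the three
nodal E-fields, with nodal fields volume-averaged over adjacent
non-electrode elements - is available as `method = "surface"`.  It is exact
for affine fields but first-order and one-sided on strongly curved mm-scale
electrodes, where it can underestimate coil currents by tens of percent at
desk resolution; it is retained because it mirrors the classical
surface-integration definition, with the reaction rule preferred for any
quantitative use.

## Metrics and statistics

"Ventricular myocardium" for the DFT mass criterion means LV + RV wall
elements, volume-weighted, excluding atrial walls and excluding
scar-labelled elements - the criterion targets excitable tissue, and a
volume (not node-count) weighting matches its tissue-mass meaning.  The
95% field level is found by explicit sort-and-accumulate over element
volumes.  DFT energies use the 100 uF capacitive-discharge formula above.

The paired Wilcoxon signed-rank test drops zero differences, assigns
mid-ranks to ties, uses the exact null distribution of the positive-rank
sum for up to 25 retained pairs (computed by convolution over doubled
ranks, so mid-ranks stay exact), and a tie-corrected,
continuity-corrected normal approximation beyond.  Two-sided p-values are
reported throughout and no multiple-testing correction is applied; each
configuration pair is read as its own pre-specified comparison.

## Degenerate inputs and tie-breaks

Geometrically impossible anatomies (wall thickness >= LVEDD/2, inward
thickening past the cavity centre) are rejected at parameter validation.
An electrode whose solid captures no lattice nodes, or exposes no surface
facets, raises a meshing error naming the electrode.  A configuration
whose coils would intersect myocardial wall labels, or whose can leaves
the subcutaneous bath, raises a placement error.  In the DFT quantile the
first element at or past the 5% cumulative volume is taken (no
interpolation), which makes the value exact under the replication oracle
and insensitive to float ties.

## Problem sizes and runtimes

The package's standard study is 5 anatomies x 4 variants x 10
configurations at h = 2.5 mm (~465k nodes, ~2.7 M tets per torso), about
200 field solves in roughly a quarter of an hour on one core; per-model
assembly is reused across configurations, and `run_cohort()` caches
finished rows on disk keyed by a content hash of all inputs so interrupted
studies resume.  The verification oracles (slab, concentric spheres at
h = 1.25 mm) run in seconds to ~1 minute.  Full-resolution runs (the
source study used 0.8 mm cardiac elements) are possible through the same
API by lowering `h`, at correspondingly higher cost.

## Known limitations

* Absolute DFT/impedance magnitudes depend on torso size and anatomical
  detail; the synthetic cohort is built for *paired, directional*
  comparisons between electrode configurations, and its absolute medians
  are smaller than those of CT-derived adult cohorts.
* The static field model carries no biphasic waveform dynamics, membrane
  kinetics, or upper-limit-of-vulnerability behaviour.
* Stair-stepped tissue interfaces (everywhere except electrode surfaces)
  limit field accuracy to first order locally; the reported metrics are
  volume integrals and are much less sensitive.
* The rule-based fibre model omits sheet/normal directions and
  apex-to-base angle variation; only the fibre axis enters the conductivity
  tensor.
* Scar representation is a parametric transmural patch, not an
  image-derived geometry, and per-scar-location subanalyses are out of
  scope.
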