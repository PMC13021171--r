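---
title: "Simulating free-flap tongue reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating free-flap tongue reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`neotongue` is a virtual testbed for free-flap tongue reconstruction after
partial glossectomy. One simulation walks the surgical timeline: a
two-layer (skin + adipose) flap is inset into the resected tongue with
virtual sutures, the viscoelastic assembly equilibrates for five minutes
("Day 0"), and one year of post-operative flap atrophy is imposed as
negative kinematic growth. The outcome of a run is the final neotongue
anatomy and the distortional strain imparted to the native tongue, and a
full-factorial driver plus a hierarchical regression layer turn batches of
runs into effect estimates for the surgical decision variables (defect
geometry, donor site, skin stiffness, overbulking).

This vignette records the science and the engineering decisions: the
constitutive models and their parameters, how suturing, sticky apposition
and atrophy are discretized, what the synthetic toy anatomy does and does
not emulate, and the numerical choices that keep the pipeline robust at
desk scale.

## Constitutive models

All tissues are nearly incompressible, isotropic and hyperelastic with
uncoupled volumetric behaviour $\tfrac{k}{2}(\ln J)^2$. The native tongue
uses a two-term Yeoh law on the deviatoric first invariant
$\bar I_1 = J^{-2/3} I_1$:
$$\Psi = c_1(\bar I_1 - 3) + c_2 (\bar I_1 - 3)^2 + \tfrac{k}{2}(\ln J)^2 ,$$
with $c_1 = 1.037$ kPa, $c_2 = 0.486$ kPa, $k = 100$ kPa. Donor skin and
subcutaneous adipose tissue use the Ogden form in the FEBio convention,
$$\Psi = \sum_i \frac{c_i}{m_i^2}
  \left(\bar\lambda_1^{m_i} + \bar\lambda_2^{m_i} + \bar\lambda_3^{m_i}
  - 3\right) + \tfrac{k}{2}(\ln J)^2 ,$$
on the deviatoric principal stretches $\bar\lambda_a = J^{-1/3}\lambda_a$.
The packaged library (`material_library()`, shipped as YAML in
`inst/extdata/materials.yaml`) holds adipose tissue
($c_1 = 9$ kPa, $m_1 = 6$) and six donor-skin profiles: three stiffness
levels per donor site, spanning reported biological variability, with
forearm skin the pliable end and thigh skin the stiff end. Second Ogden
coefficients printed in Pa are converted to kPa on load; two thigh
profiles carry negative $c_2$, which is admissible because the implied
small-strain shear modulus (checked numerically at construction) remains
positive. The unit system is mm-kPa-s; 1 kPa x 1 mm^2 = 1 mN.

Stress evaluation is analytic: invariant derivatives for Yeoh, a spectral
(principal-stretch) formula for Ogden. The spectral route is well defined
at coincident stretches because the principal Kirchhoff values depend
symmetrically and continuously on the stretches; no eigenvalue
perturbation is needed for the stress itself, and element tangents are
finite differences of the exact internal force (see below), so the
degenerate locus needs no special-casing there either.

Viscoelasticity is quasi-linear with a Prony relaxation function
$G(t) = 1 + \sum_i \gamma_i e^{-t/\tau_i}$ acting on the deviatoric
elastic stress through the hereditary integral. The discrete update is the
standard one-step exponential recursion with midpoint weighting of the
stress increment: exact for pure decay, first-order during ramps. The
five-minute Day-0 equilibration is justified by `relaxation_completion()`:
at $t = 300$ s the transient is 97.1% complete for tongue, 97.8% for skin
and 100% for adipose tissue, so the Day-0 state is effectively the
long-term equilibrium.

## Toy anatomy and flap assembly

No deposited anatomies exist, so the synthetic-data generator
(`generate_toy_anatomy()`) builds a convex tongue-like solid: a structured
hexahedral grid, each cell split into six conforming tetrahedra, smoothly
mapped onto an ellipsoid of 60 x 50 x 40 mm default extent. The grid is
graded so the outermost lateral layer is one skin thickness (2.5 mm),
giving the flap a genuinely thin skin shell even on coarse meshes. Four
case styles (A-D) mimic tip-sparing lateral, full lateral, posteriorly
extended and midline-crossing resections by ranking cells with a
case-specific score and removing the top-scoring cells until the requested
volume fraction (default 25%) is met; because the resection is an exact
element partition, resected + resection volumes add to the tongue volume
to machine precision. The attachment node set on the inferior face stands
in for the mandibular/hyoid muscular attachments and removes rigid-body
modes.

The flap (`build_flap()`) is the resection solid itself, re-instanced as
an independent body: the interface is node-congruent with the cavity by
construction, which gives exact suture and tie correspondences. Elements
within one skin thickness of the original tongue exterior become `skin`;
the rest is `adipose`.

**Overbulking** is the enlargement of the flap's stress-free subcutaneous
configuration. The default realization keeps the mesh congruent and
records the level as a kinematic growth *prestretch*: before suturing, the
adipose region receives a transversely isotropic growth tensor
$F_g = I + (a - 1)\, d\otimes d$ along the flap thickness direction $d$,
with $a$ calibrated (a few fixed-point iterations) so the realized adipose
volume gain equals the level exactly. This is mathematically identical to
meshing a thicker adipose slab, but it leaves the skin paddle's reference
dimensions untouched -- deliberately isolating flap bulk from skin paddle
size -- and it lets atrophy return the flap to a geometrically compatible
configuration. A purely geometric variant
(`build_flap(realize = "geometry")`) materializes the enlarged mesh by
solving the same growth problem on the standalone flap with a soft
surrogate material; it exists for volume-bookkeeping checks and export.
Earlier direct approaches (scaling node positions along the thickness
axis) were abandoned: on the staircase cut of a structured grid they
invert elements, and resetting the reference onto an inflated geometry
bakes a stretched skin dome into the flap that atrophy can no longer
deflate.

## Virtual suturing and sticky apposition

Suture points are laid on the resection rim at 5 mm target spacing
(`place_suture_points()`: count = perimeter/spacing rounded, minimum 3,
re-spaced exactly equally). Each suture engages a cluster of surface nodes
within a 2 mm radius rather than a single node, to avoid artificial stress
concentrations; on meshes coarser than the clinical scale both numbers are
enlarged to the local edge length so clusters are never empty. Cluster
forces are distributed by linear *vector* springs (resisting change of the
relative position vector) connecting cluster nodes to a virtual center
node -- the vector form is smooth at zero length, which matters because
one-node clusters place the center on the node itself. The paired centers
are drawn together by one-dimensional tension elements whose rest length
ramps linearly to 0.02 mm over the stage; increments that fail to converge
are bisected automatically. Cluster stiffness defaults to 30x the local
small-strain modulus times the cluster radius, followed by a 25x stiffening
("lock") of the tension elements once the rims are apposed; this meets the
0.1 mm final-gap contract at a tenth of the Newton cost of using the
stiffest springs throughout.

"Sticky" apposition is realized as node tying: every congruent interface
node pair whose gap falls below a reach threshold (0.2 mm, enlarged with
the mesh size on coarse toys) is joined by a zero-rest-length spring.
Engagement is progressive -- each round of ties pulls more pairs within
reach -- and gentle: a newly engaged tie starts as an axial spring whose
rest length ramps from the current gap to zero. A unilateral plane
constraint lateral to the pre-operative tongue surface stands in for the
rigid jaw/cheek wall (penalty force on crossing nodes), replacing full
rigid-body contact.

## Atrophy as negative kinematic growth

Post-operative flap atrophy is a time-dependent, isotropic negative
kinematic growth of the flap's subcutaneous elements: $F = F_e F_g$ with
$F_g$ scaled down from the overbulking prestretch, stress derived from
$F_e$ only. A clinically representative total loss of 40% over one year is
the default. Because constraint interaction (ties, bulk penalty, the
wall) makes the realized volume differ slightly from the determinant law,
the growth scale is calibrated iteratively until the measured deformed
volume loss matches the target within 2%. Two accounting conventions are
exposed: `"adipose"` (default) applies the loss to the adipose region --
the convention under which the 66.7% overbulking level exactly compensates
40% atrophy, since the overbulked component is the one that atrophies --
and `"flap"` applies it to the whole flap, which on a toy with a
non-negligible skin fraction leaves a residual deficit of
$0.4\,V_{skin}$. The pseudo-time ramp uses a handful of relaxed
(long-term) solves; the paper-scale one-year horizon carries no separate
physics here because the end state is an equilibrium.

## Outcome metrics

*Anatomical deviation* is the 99th-percentile Hausdorff distance between
the final neotongue surface (exterior of both bodies, interface patches
excluded) and the pre-operative tongue surface, computed on about 10^4
quasi-uniform deterministic samples per surface with exact point-to-
triangle distances; the symmetric (max of directed percentiles) variant is
the default and both directed variants are exposed. The percentile makes
the metric robust to isolated mesh irregularities while retaining the
largest regional deviation; it is monotone in the percentile and recovers
the classic Hausdorff distance at $q = 1$.

*Imposed deformation* is the von Mises equivalent strain
$\varepsilon_{eq} = \sqrt{\tfrac23\,\mathrm{dev}E : \mathrm{dev}E}$ of the
Lagrange strain, reported as a maximum over the native region. Being
purely distortional it ignores the uniform volumetric shrinkage of the
atrophying flap. Two maxima are recorded: the raw maximum, and a guarded
maximum that excludes native elements touching the interface or a suture
cluster (where the discrete springs and ties concentrate stress by
construction) plus the top 0.1% of values. The guarded figure is the
primary outcome; the raw one is kept for sensitivity.

## Numerical design

The solver is a total-Lagrangian implicit quasi-static Newton iteration
with line search, automatic load/step bisection, and sparse direct linear
solves. Linear (tet4) elements are the default for toy studies; quadratic
tet10 elements (4-point quadrature, consistent -V/20 / V/5 body-force
lumping) are available for verification and anti-locking, and pass the
classical patch test to 1e-8 on jittered grids. Element tangents are
forward finite differences of the exact analytic internal force -- the
stress code is the single source of truth, and the tangent is verified
against global residual differences in the tests. Floating bodies during
flap approach are regularized by weak grounding springs (0.01 mN/mm per
node) that are dropped for the final solves. Convergence demands a
residual below `1e-6` of the load scale (absolute floor `1e-7` mN).
Determinism: identical inputs reproduce converged nodal positions to
1e-8; Newton trajectories are not required to be bitwise identical.

Problem sizes are chosen for a desk-scale study: the default factorial
toy uses a 6 x 5 x 4 grid (about 1,400 native + 700 flap tetrahedra), a
single reconstruction completing in roughly 15 s; verification fixtures
use single cells to a few hundred elements; surface metrics use 10^4
samples. The test-suite factorial restricts itself to one defect case,
six stiffness profiles and three overbulking levels.

Mesh-convergence studies use the generator's `refine` argument: each
coarse cell is subdivided per axis while the resection is still selected
at the coarse level, so every density meshes the *same* parametric
geometry, and the suture spacing, cluster radius and tie reach are fixed
across densities so only the discretization changes. (Refining the
divisions directly would change the staircase cut itself and the suture
count with it, confounding the study.)

## Calibration module

`fit_ogden()` fits two-term Ogden models to uniaxial stress-stretch
curves, mirroring the donor-skin parameterization workflow: a seeded
differential-evolution search (rand/1/bin, population 40, 200 generations
by default) over a parameter box, followed by an L-BFGS-B polish, with a
penalty rejecting candidates whose small-strain modulus is non-positive.
The objective is the RMS stress misfit on the target grid; the target
stress measure (nominal by default, Cauchy optional) is configuration
because the aggregated experimental literature does not report a single
convention. Parameter non-identifiability is expected and accepted --
curve misfit, not parameter recovery, is the quality criterion.
`build_stiffness_levels()` fits ordered low/mid/high bands (mean +-
SD-style constructions) and warns on crossing targets. Fits are
deterministic given a seed and leave the caller's RNG stream untouched.

## Statistical analysis

`enumerate_design()` spans the full 4 x 6 x 5 = 120-cell factorial;
`encode_design()` produces treatment dummies for the defect case
(reference A), overbulking as a continuous fraction, a binary `is_thigh`
and an ordinal `stiffness_level` in {-1, 0, +1} -- the six stiffness
profiles decompose exactly into the latter two. `fit_hierarchy()` fits a
main-effects model and one augmented with the scientifically relevant
two-way interactions (all pairs among overbulking, donor and stiffness,
plus overbulking x case; case x donor and case x stiffness are excluded by
default and configurable), selects by nested ANOVA F-test, and reports
variance inflation factors (flagged above 10) and Q-Q residual data for
visual normality inspection -- no automatic normality rejection.
Overbulking is encoded as a fraction (0-0.889); a percent scale would
simply rescale its coefficients by 1/100. The machinery is validated by
Monte-Carlo parameter recovery and type-I-error calibration of the F-test
on synthetic outcomes (`synthesize_outcomes()`), never by re-using the
fitted values themselves.

## What the toy fixtures do and do not show

The generator emulates the *structure* of the study: a convex tongue with
a sizeable lateral defect, a congruent two-layer flap, literature-style
material contrast between donors and stiffness levels, suture-driven
insetting, sticky interface apposition and calibrated atrophy. Passing
tests therefore demonstrate that the machinery -- constitutive laws,
solver, staging, metrics, statistics -- behaves correctly and that the
main qualitative trade-offs emerge: overbulking restores the pre-operative
anatomy (negative deviation effect, with the 66.7% level leaving the final
volume within a few percent of the pre-operative tongue), and thigh donors
and stiffer skin impose more strain on the native tongue.

The toy does not claim anatomical fidelity, and one directional finding
does not transfer: on this fixture the maximum native strain *decreases*
with overbulking. At low overbulk the dominant strain source is the
atrophy deficit -- the shrinking flap, tied to the soft native wedge,
drags its walls -- while near-compensating overbulk minimizes that
deficit; the squeeze that a bulky flap exerts inside a concave,
jaw-confined patient anatomy is only weakly represented by the toy's
planar cavity and unilateral wall. Reproducing a squeeze-dominated strain
response requires the concave patient geometry itself, which is outside
the generator's scope.

Other known limitations: no muscle activation or anisotropy (by design --
the end states are passive equilibria), no frictional or self-contact, no
scar-tissue stiffening at the incisions, node ties rather than a true
sticky penalty interface, and coarse linear tetrahedra for the factorial
runs (quadratic elements are available but reserved for verification
given their cost).

## Reproducing the study conditions

```{r, eval = FALSE}
library(neotongue)

lib <- material_library()
relaxation_completion(lib$tongue, 300)      # 97.1%

run <- run_reconstruction(run_config(case = "A", donor = "forearm",
                                     stiffness_level = 0, overbulk = 0.667))
run$outcome

design <- enumerate_design()                # the 120-cell factorial
out <- sweep_reconstructions(design[1:10, ], out_dir = tempdir())
h <- fit_hierarchy(encode_design(out), "deviation_p99")
coef_table(h)
```
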