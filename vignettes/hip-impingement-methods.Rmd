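---
title: "Simulating AIIS/subspine impingement and the pelvic-tilt effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating AIIS/subspine impingement and the pelvic-tilt effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

In femoroacetabular impingement syndrome (FAIS), the proximal femur abuts
the acetabular rim or the anterior inferior iliac spine (AIIS)/subspine
region during ordinary hip motion. Posterior pelvic tilt rotates the
anterosuperior pelvis away from the flexing femur and is a candidate
conservative (physiotherapy) target. `hipimpinge` implements a bone-only
computer simulation of this mechanism: parametric hip models are posed
through 12 activity-of-daily-living (ADL) postures under three pelvic tilt
conditions, bone-on-bone contact is detected on triangle meshes, contacts
are classified into three acetabular regions, per-patient impingement
incidence is computed, and the tilt effect is quantified with
random-intercept linear mixed models adjusted for anatomy.

The pipeline mirrors a clinical CT-based simulation study design. Since no
patient geometry is deposited with such studies, the package includes a
fully parametric anatomy generator whose population defaults reproduce the
emulated cohort distributions (femoral version 14.19 ± 10.84°, acetabular
version 18.63 ± 6.34°, LCEA 30.77 ± 6.55°, alpha angle 67.13 ± 8.89°, AIIS
type I:II = 28:50). Everything downstream — the ROM engine, region map,
incidence statistics and mixed models — works identically on user-supplied
STL/PLY meshes with a landmark JSON file.

## The parametric bone model

Both bones are *radial solids*: the boundary is a single-valued radial
function of direction from a fixed center. This gives watertight meshes by
construction (a polar grid sampled from the radial function), an exact
point-membership test used by the voxel-overlap test oracle, and a direct
mapping from each anatomical parameter to one constructive control.

**Femur** (center = femoral head center): the radial hull of

* a head sphere of radius $R$ (`head_radius`, default 24 mm),
* a neck capsule along the neck axis, oriented by the neck-shaft angle
  (default 128°) and the femoral version (rotation about the mechanical
  axis); its radius is $1.02\,R\sin(\min(\alpha, 42^\circ))$ so that for
  sub-cam alpha angles the head-neck contour exits the 2%-tolerance head
  sphere exactly at the requested alpha arc (the classical sphere-cylinder
  tangency),
* a proximal shaft capsule below the neck base,
* for $\alpha > 42^\circ$, a cam prominence: a spherical-cap thickening
  whose height ramps up at 0.12 mm/deg inside the alpha arc (capped at
  4 mm), centered on the anterosuperior quadrant of the head-neck junction.
  The ramp origin is offset so the surface crosses the 2% sphericity
  tolerance exactly at the requested alpha angle; the measured alpha is
  therefore the requested one by construction, up to mesh discretization.

**Pelvis** (center = acetabular center): a two-sheet radial shell. The
inner sheet is the acetabular cup — a spherical socket of radius
$R + 1$ mm (a cartilage-free clearance; the model is bone-only, so the
joint is a concentric ball-in-socket with 1 mm of free space) — which
flares away from the joint beyond the rim. The outer sheet is the cortex at
a fixed 8 mm plate thickness and carries the AIIS prominence, a smooth
compact bump (8 mm high, 22° support). A side wall closes the plate.

Three conventions deserve explanation:

* *Cup orientation and coverage.* The cup axis has a fixed anatomic
  inclination (38° above medial) and is rotated about the cranial axis by
  the acetabular version. The coverage half-angle is then solved
  (1-D root find) so that the lateral center-edge angle measured on the rim
  landmarks — the roof-edge protocol, the angle from vertical of the most
  lateral superior rim sample in the coronal projection — equals the
  request. Coverage, not axis elevation, is what LCEA measures clinically,
  and this mapping stays monotone over the full 5-55° range.
* *Plate extent.* Periacetabular bone recedes from the joint quickly except
  toward the AIIS. The plate's angular width beyond the rim is therefore
  azimuth-dependent: 22° in the AIIS sector, falling off (Gaussian, 50°
  scale) to 8° elsewhere, with the inner sheet flaring radially by up to
  40 mm at the local plate edge. Early versions with an azimuth-uniform
  plate produced spurious neck-on-plate contacts at 90° flexion that no
  real hip shows; the azimuth-shaped plate restores realistic bone-only
  ROM (a no-cam hip flexes to ~120° and clears 30° internal rotation at
  all nine IR conditions).
* *AIIS morphotype.* The prominence apex's polar angle is solved so its
  height relative to the acetabular rim plane encodes the Hetsroni type:
  6 mm above the plane (type I), at the plane (type II), 4.5 mm beyond it
  (type III; capped for shallow cups where the plate cannot carry the apex
  that far — apexes are always at least 1 mm beyond the plane, otherwise
  the combination is reported as infeasible). The study cohort contained no
  type III hips; type III generation is an extrapolation provided for
  completeness.

The generator's contract — tested property, not aspiration — is that the
measurement suite (`measure_alpha_angle()`, `measure_lcea()`,
`measure_acetabular_version()`, `measure_femoral_version()`) recovers the
requested parameters from the generated meshes and landmarks within 2°.
Cohort covariate tables carry the *measured* values. Left hips are exact
mirror images of right hips through the sagittal plane.

The alpha measurement deserves one note: it fits a sphere to the head polar
cap, then finds where mesh edges cross the 1.02 R sphere, scanning the
anterosuperior (cam-side) profile only — the posteroinferior azimuths would
pick up the intertrochanteric silhouette, which is not part of the
radiographic head-neck contour.

## Frames, tilt and posing

The functional pelvic plane (FPP) is built from the bilateral ASIS
landmarks and the CT table axis: lateral = right-to-left ASIS direction,
cranial = CT Z orthogonalized against it, anterior completes the
right-handed triad. (The classic anterior pelvic plane uses the pubic
tubercles instead; that variant is not the default because the simulation
protocol is defined on the ASIS + CT-Z plane.)

Pelvic tilt is a rotation of the pelvis about the FPP lateral axis
*through the femoral head center*, so the joint center is invariant and
tilt changes only the relative bone orientation; any other axis would
conflate tilt with joint translation. Sign convention: **positive tilt =
posterior tilt** (the ASIS pair rotates posteriorly), matching the sign of
the fitted tilt coefficient.

Postures use the clinical intrinsic sequence: flexion about the (tilted)
pelvic lateral axis, then adduction about the floating anteroposterior
axis, then internal rotation about the femoral long axis — the order in
which the protocol fixes flexion and adduction and sweeps IR. The net
rotation is the product of the three fixed-axis matrices and is checked in
the tests against an independently composed closed form.

## Collision detection and the ROM search

Meshes collide when any triangle pair intersects (Möller interval test,
uniform-grid broadphase over the static pelvis, implemented in C++). Two
symmetric masks express that a congruent ball-in-socket joint is "in
contact" articularly without impinging: pelvis faces on the cup surface
(inside the rim minus a 2° margin, within 3 mm of the cup radius) and
femur faces on the spherical head surface are excluded. Only
extra-articular contact counts as impingement. Contact points are
length-weighted centroids of the intersection segments on the pelvis
surface, grouped into connected patches; the largest patch is reported
(multiplicity is logged), which also makes regional counts sum exactly to
the total count.

The 12-condition ADL protocol: maximum flexion (threshold 130°) at
adduction 0/10/20°, and maximum internal rotation (threshold 30°) at
flexion 90/70/45° × adduction 0/10/20°. Each search marches the swept
angle in 1° steps from zero and bisects the first colliding interval to
0.1°; if nothing collides by the threshold the condition does not impinge
and the limiting angle equals the cap. A configuration already colliding at
the start posture is recorded as impinged at 0° with a baseline flag, not
an error, so extreme synthetic anatomies cannot crash cohort runs.

Incidence is `count / 12 × 100` per region and in total, always on the
lattice of multiples of 100/12.

## Region classification

The impingement site is classified in the lateral (sagittal) view, as the
clinical region definition is a 2D construction: project the contact point
onto the plane orthogonal to the pelvic lateral axis and take its angle
about the acetabular center. Region A (AIIS/subspine) is the wedge between
the rays through the two inflection landmarks flanking the AIIS (ASIS-AIIS
and AIIS-rim); wedge boundaries belong to A (conservative toward detecting
AIIS involvement; flip-able by the user via the sector object). Region B is
the arc anterior(-inferior) to the wedge down to the inferior rim extreme
(the projection of the rim sample most distal along the negative cranial
axis — a logged convention for the B/C cut); region C is the remaining
posterolateral arc. Sectors move rigidly with the pelvis, so classification
commutes with tilt.

## The statistics layer

Each patient contributes one AIIS-region incidence per tilt (-10°, 0,
+10°); patients are random intercepts. The model is
$y_{ij} = x_{ij}'\beta + b_i + e_{ij}$ with REML estimation. Because the
random structure is a single intercept, the profiled REML/ML criteria have
closed per-patient forms and the fit reduces to a 1-D optimization over the
variance ratio; estimates, standard errors, and REML/ML log-likelihoods
match `lme4`/`lmerTest` to ~1e-8 on the frozen benchmark datasets shipped
with the package, and Satterthwaite degrees of freedom (delta method on the
coefficient variance with respect to the two variance components, observed
information from a numerical Hessian of the unprofiled REML likelihood)
match to better than 1e-4.

Model comparison reproduces the clinical analysis layout: four univariate mixed
models (AIIS type, femoral version, tilt, LCEA), the multivariable
fixed-effects regression, and the multivariable mixed model. The
"multivariate linear-mixed model" of the source design is read as a
*multivariable* (multiple-covariate, scalar-response) model — the response
is a single incidence, reported as one coefficient column.
Conditional AIC follows Vaida-Blanchard: $-2\,\ell_c + 2(\rho + 1)$ where
$\ell_c$ is the conditional (BLUP-level) Gaussian log-likelihood and
$\rho$ the trace of the hat matrix mapping observations to conditional
fitted values. cAIC, BIC and deviance are computed from ML refits so they
are comparable across fixed-effect structures; REML is used for the
reported estimates. At a zero intercept variance $\rho$ collapses to the
fixed-effects rank and cAIC equals the marginal AIC of the fixed-effects
model, which the tests verify.

The generative simulator (`incidence_generator()`) draws covariates from
the cohort distributions and responses from the mixed-model
data-generating process with effect defaults anchored to the fitted
coefficient scale (tilt -0.8 %/deg, AIIS type I +6.7%, femoral version
-0.7 %/deg, acetabular version +0.06 %/deg, LCEA +0.6 %/deg; intercept SD
15%, residual SD 10%). Responses are truncated to [0, 100]; the intercept
default (48% at neutral tilt, type II, mean covariates) centers the
response so that under the defaults fewer than 2% of draws truncate (the
realized fraction is recorded on every simulated table). Truncation is the
one place the generative model deviates from linearity; at the default
rate its bias on the recovered tilt slope is about 0.015 %/deg, well
inside the ±0.05 acceptance band of the recovery study. An optional switch
rounds responses to the 100/12 incidence lattice.

## What the synthetic data do and do not show

The generator emulates the *geometry-to-incidence* mechanism: cam size,
coverage, version, AIIS morphology and pelvic tilt interact through actual
collision detection, not through an assumed regression. A 20-hip cohort at
the emulated distribution reproduces the qualitative structure of the
clinical results: the AIIS/subspine region is the most frequent site, and
its mean incidence decreases monotonically from anterior to posterior tilt
(the central finding), with totals in the clinically reported range.

It does not emulate: real cortical geometry (smooth parametric surfaces
only), soft tissues (capsule, labrum, muscle — absent from the emulated
bone-only design too, which is known to overestimate ROM), CT segmentation
noise, or morphological covariance beyond the parameter level (parameters
are drawn independently). Passing tests therefore validate the method
pipeline and its statistical layer, not patient-level prediction.

## Numerical choices

* Mesh resolution: 1.5 mm default edge length (matching a 1.5 mm CT slice
  protocol); cohort-level studies in the tests and acceptance script use
  2.0 mm, which leaves measured anatomy within the 2° contract and changes
  limiting angles by well under a degree, at roughly half the cost. The
  problem sizes used by the shipped studies are 20 hips × 3 tilts × 12
  conditions (simulation), 200 simulated cohorts of 78 patients (recovery),
  and 100 cohorts (model comparison).
* ROM search: 1° coarse march, 0.1° bisection tolerance — below mesh and
  landmark precision.
* Collision broadphase cell size: 1.5 × mean triangle extent.
* Parameter clipping in cohort sampling: draws outside the feasible ranges
  (e.g. alpha outside [32, 98]°) are clipped and counted; explicitly
  infeasible combinations (a type III apex on a very shallow cup) are
  redrawn, capped at 100 attempts.
* REML optimization: 1-D golden-section/parabolic search over log variance
  ratio in [-12, 12], with an explicit boundary check at zero.
* Degenerate inputs: coincident ASIS landmarks, CT axis parallel to the
  ASIS line, zero-length neck axes, non-watertight meshes, singular designs
  and variance-free tilt grids all raise named errors; the boundary
  (zero intercept variance) fit is returned with a flag, with residual
  degrees of freedom substituted for Satterthwaite.

## Known limitations

* The radial-solid pelvis is a local periacetabular model; structures far
  from the joint (ischium, pubic ramus, iliac wing) are not meshed, so
  extra-articular impingement outside the modeled plate (e.g.
  ischiofemoral) is out of scope.
* Region classification is projection-based, exactly as the 2D region
  definition prescribes; a 3D geodesic definition would draw slightly
  different B/C boundaries.
* The mixed model treats incidence as continuous Gaussian, as in the
  emulated analysis; with 12 conditions the response is coarsely discrete,
  and the Monte-Carlo recovery study shows the practical consequences are
  negligible at these effect sizes.
* One condition can in principle touch two regions at once; the engine
  reports the largest contact patch only, so regional counts always sum to
  the total (logged when multiple patches occur).
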