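# hipimpinge

Bone-on-bone hip impingement simulation and pelvic-tilt analysis in R.

In femoroacetabular impingement syndrome (FAIS), the proximal femur abuts
the acetabular rim or the anterior inferior iliac spine (AIIS)/subspine
region during daily motion, and posterior pelvic tilt is a candidate
conservative strategy for avoiding that contact. `hipimpinge` implements
the full computational pipeline for studying this mechanism:

1. **Synthetic anatomy** — watertight parametric pelvis/femur surface
   meshes with embedded landmarks. Shape parameters are the clinical
   measurements themselves: alpha angle (cam severity), lateral
   center-edge angle (LCEA), acetabular and femoral version, Hetsroni AIIS
   morphotype, head radius, neck-shaft angle. Cohort sampling defaults to
   the emulated study population (alpha 67.13 ± 8.89°, LCEA 30.77 ± 6.55°,
   AV 18.63 ± 6.34°, FV 14.19 ± 10.84°, AIIS I:II = 28:50). User meshes
   (binary STL / PLY plus a landmark JSON) drop into the same pipeline.
2. **Frames and tilt** — the functional pelvic plane (bilateral ASIS +
   CT Z axis), femoral frames, and pelvic tilt as a rotation about the FPP
   lateral axis through the hip rotation center. Positive tilt = posterior.
3. **ROM engine** — the femur is posed by flexion → adduction → internal
   rotation about the joint center; triangle-mesh collision (C++
   broadphase + exact triangle intersection) with articular-surface
   masking finds the maximal collision-free angle (1° march, 0.1°
   bisection) for the 12-condition activities-of-daily-living protocol
   (max flexion < 130° at adduction 0/10/20°; max internal rotation < 30°
   at flexion 90/70/45° × adduction 0/10/20°).
4. **Region map** — contacts are classified in the sagittal projection
   into region A (AIIS/subspine wedge between the two inflection-point
   rays), B (anterior) or C (posterolateral).
5. **Incidence statistics** — incidence = impingement count / 12 × 100 per
   region, long-format cohort tables, per-tilt summaries and anatomical
   subgroup tables.
6. **Mixed models** — the AIIS-region incidence is modeled as
   y_ij = x_ij'β + b_i + e_ij with a random intercept per patient, REML
   estimation, Satterthwaite degrees of freedom, Vaida–Blanchard
   conditional AIC, a six-candidate model comparison, and a generative
   simulator for parameter-recovery studies.

See `vignettes/hip-impingement-methods.Rmd` for the model, its
assumptions, and all numerical conventions.

## Worked example

Generate the cohort-mean hip, run the ADL protocol under three pelvic tilt
conditions, and fit the mixed model on a simulated cohort:

```r
library(hipimpinge)

hip <- generate_hip(anatomy_params(alpha_angle = 67.13, lcea = 30.77,
                                   acetabular_version = 18.63,
                                   femoral_version = 14.19, aiis_type = "II"))
hip
#> hip_model (right hip, tilt +0.0 deg)
#>   pelvis: 40068 faces | femur: 16160 faces | resolution 1.5 mm
#>   measured: alpha 67.1, LCEA 30.8, AV 18.6, FV 14.2 (deg)

for (tau in c(-10, 0, 10)) {
  inc <- compute_incidence(run_protocol(hip, tau))
  cat(sprintf("tilt %+3d: A %5.1f%%  B %5.1f%%  C %5.1f%%  total %5.1f%%\n",
              tau, inc$incidence_pct[1], inc$incidence_pct[2],
              inc$incidence_pct[3], inc$incidence_pct[4]))
}
#> tilt -10: A  50.0%  B  25.0%  C   0.0%  total  75.0%
#> tilt  +0: A  33.3%  B  25.0%  C   0.0%  total  58.3%
#> tilt +10: A  25.0%  B  16.7%  C   0.0%  total  41.7%
```

The measured anatomy round-trips the request (the generator's 2° contract),
and the AIIS/subspine region (A) is the dominant impingement site, its
incidence falling as the pelvis tilts posteriorly — 6 of 12 conditions
impinge in region A at 10° anterior tilt, 3 of 12 at 10° posterior tilt.

```r
tab <- simulate_incidence(incidence_generator(n_patients = 78, seed = 1))
fit <- fit_mixed(tab)
fit
#> random-intercept mixed model (REML): 234 obs, 78 patients
#>   sigma_b^2 = 214.994, sigma_e^2 = 110.904
#>                term    beta     se       df       t      p  ci_low ci_high
#>         (Intercept) 38.6946 9.6285  72.9988  4.0188 0.0001 19.5051 57.8841
#>            tilt_deg -0.7829 0.0843 154.9994 -9.2855 0.0000 -0.9495 -0.6164
#>          aiis_typeI  1.6016 3.7317  72.9988  0.4292 0.6690 -5.8356  9.0389
#>     femoral_version -0.5473 0.1884  72.9988 -2.9052 0.0049 -0.9228 -0.1719
#>  acetabular_version  0.4264 0.3235  72.9988  1.3179 0.1917 -0.2184  1.0711
#>                lcea  0.4302 0.2618  72.9988  1.6434 0.1046 -0.0915  0.9519
#>   logLik(REML) -954.03 | deviance(ML) 1909.42 | cAIC 1835.79 | BIC 1953.06
```

Each degree of posterior pelvic tilt lowers the AIIS-region incidence by
about 0.8 percentage points (95% CI −0.95 to −0.62) after adjusting for
anatomy — the generative truth (−0.8 %/deg) is recovered. The
six-candidate comparison (`compare_models(tab)`) selects the multivariable
mixed model by conditional AIC.

A whole cohort run — meshes to coefficient tables — is one call:

```r
run_pipeline(run_config(seed = 1, n_patients = 20, out_dir = "hip_run"))
```

which writes `cohort.csv`, `records.csv`, `incidence.csv`, the summary and
subgroup tables, `coefficients.csv`, `model_comparison.csv`,
`tilt_profile.csv` and a settings log. A thin CLI over the same functions
is in `inst/cli/hip-impinge.R`.

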