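test_that("generated hips round-trip the requested anatomy within 2 degrees", {
  h <- mean_hip()
  m <- h$measured
  expect_lt(abs(m$alpha_angle - 67.13), 2)
  expect_lt(abs(m$lcea - 30.77), 2)
  expect_lt(abs(m$acetabular_version - 18.63), 2)
  expect_lt(abs(m$femoral_version - 14.19), 2)

  set.seed(41)
  done <- 0
  while (done < 6) {
    p <- anatomy_params(
      alpha_angle = runif(1, 35, 90), lcea = runif(1, 12, 50),
      acetabular_version = runif(1, 3, 35), femoral_version = runif(1, -10, 40),
      aiis_type = sample(c("I", "II", "III"), 1),
      head_radius = runif(1, 20, 28))
    # explicitly infeasible combinations are redrawn, as in cohort sampling
    h <- tryCatch(generate_hip(p, resolution = 2.0), error = function(e) {
      expect_match(conditionMessage(e), "infeasible")
      NULL
    })
    if (is.null(h)) next
    done <- done + 1
    m <- h$measured
    expect_lt(abs(m$alpha_angle - p$alpha_angle), 2)
    expect_lt(abs(m$lcea - p$lcea), 2)
    expect_lt(abs(m$acetabular_version - p$acetabular_version), 2)
    expect_lt(abs(m$femoral_version - p$femoral_version), 2)
    expect_true(isTRUE(is_watertight(h$pelvis)))
    expect_true(isTRUE(is_watertight(h$femur)))
  }
})

test_that("all required landmarks are present on generated meshes", {
  h <- mean_hip()
  expect_true(all(hipimpinge:::required_pelvis_landmarks %in%
                    names(h$pelvis$landmarks)))
  expect_gte(sum(grepl("^acetabular_rim_", names(h$pelvis$landmarks))), 12)
  expect_true(all(hipimpinge:::required_femur_landmarks %in%
                    names(h$femur$landmarks)))
})

test_that("a sub-threshold alpha angle leaves the head spherical", {
  h <- nocam_hip()
  V <- h$femur$vertices
  fs <- h$internals$femur_solid
  a <- fs$a
  r <- sqrt(rowSums(V^2))
  psi <- acos(pmax(-1, pmin(1, (V %*% a) / r))) * 180 / pi
  arc <- psi > 50 & psi < 160          # head region beyond the neck junction
  sp <- hipimpinge:::fit_sphere(V[arc, ])
  dev <- abs(sqrt(rowSums(sweep(V[arc, ], 2, sp$center)^2)) - sp$radius)
  expect_lt(max(dev), 0.5)
})

test_that("alpha measurement matches the sphere-cylinder closed form", {
  # a femur that is exactly head sphere + neck cylinder: the contour exits
  # the tolerance sphere at asin(rho / (1.02 R))
  R <- 24
  for (alpha_req in c(35, 40)) {       # below the cam onset: pure tangency
    h <- cached_hip(paste0("ncam", alpha_req),
                    anatomy_params(alpha_angle = alpha_req), 2.0)
    rho <- h$internals$femur_solid$rho
    analytic <- asin(rho / (1.02 * h$internals$femur_solid$R)) * 180 / pi
    expect_lt(abs(measure_alpha_angle(h) - analytic), 1.0)
  }
  # generator round-trip at the clinical cam boundary and a severe cam
  for (alpha_req in c(55, 80)) {
    h <- cached_hip(paste0("cam", alpha_req),
                    anatomy_params(alpha_angle = alpha_req), 2.0)
    expect_lt(abs(measure_alpha_angle(h) - alpha_req), 2)
  }
})

test_that("left hips are exact sagittal mirror images of right hips", {
  pr <- anatomy_params(side = "right")
  pl <- anatomy_params(side = "left")
  hr <- cached_hip("mirror_r", pr, 2.5)
  hl <- cached_hip("mirror_l", pl, 2.5)
  for (bone in c("pelvis", "femur")) {
    vr <- hr[[bone]]$vertices
    vr[, 2] <- -vr[, 2]
    expect_lt(max(abs(vr - hl[[bone]]$vertices)), 1e-6)
  }
  # mirroring swaps the left/right ASIS labels
  expect_equal(hl$pelvis$landmarks$ASIS_left,
               hr$pelvis$landmarks$ASIS_right * c(1, -1, 1))
  ml <- hl$measured
  expect_lt(abs(ml$femoral_version - 14.19), 2)
  expect_lt(abs(ml$lcea - 30.77), 2)
})

test_that("AIIS morphotype controls the prominence height against the rim plane", {
  heights <- sapply(c("I", "II", "III"), function(ty) {
    h <- cached_hip(paste0("aiis", ty), anatomy_params(aiis_type = ty), 2.5)
    ps <- h$internals$pelvis_solid
    o <- -ps$a_cup                      # opening direction
    rim <- hipimpinge:::rim_samples(h$pelvis)
    plane <- mean(rim %*% o)
    sum(h$pelvis$landmarks$AIIS_apex * o) - plane
  })
  expect_lt(heights[["I"]], -2)              # above the rim plane
  expect_lt(abs(heights[["II"]]), 1.5)       # at the rim
  expect_gt(heights[["III"]], 2)             # extends below the rim plane
})

test_that("cam volume outside the head sphere grows strictly with alpha", {
  # quadrature over a fixed direction grid of the generated solids
  set.seed(5)
  U <- matrix(rnorm(3 * 20000), ncol = 3)
  U <- U / sqrt(rowSums(U^2))
  vol <- sapply(c(50, 60, 70, 80), function(alpha) {
    fs <- hipimpinge:::femur_solid(alpha, 14.19, 24)
    # restrict to the head-neck region (exclude neck/shaft exits)
    r <- hipimpinge:::femur_radial(U, fs)
    psi <- acos(pmax(-1, pmin(1, U %*% fs$a))) * 180 / pi
    sel <- psi > 50
    mean(pmax(r[sel]^3 - fs$R^3, 0)) * 4 * pi / 3
  })
  expect_true(all(diff(vol) > 0))
})

test_that("cohort sampling is deterministic and matches the target distribution", {
  spec <- cohort_spec(n_patients = 78, seed = 7)
  co1 <- sample_cohort(spec, resolution = 3.0, quiet = TRUE)
  co2 <- sample_cohort(spec, resolution = 3.0, quiet = TRUE)
  expect_identical(co1$covariates, co2$covariates)
  fv <- co1$covariates$femoral_version
  expect_lt(abs(mean(fv) - 14.19), 3 * 10.84 / sqrt(78) + 2)
  expect_true(all(co1$covariates$aiis_type %in% c("I", "II")))
  # covariates carry the measured anatomy, not the request: they differ from
  # the exact normal draws but stay near the cohort center
  expect_lt(abs(mean(co1$covariates$lcea) - 30.77), 3 * 6.55 / sqrt(78) + 2)
})

test_that("a zero-variance cohort reproduces the mean anatomy exactly", {
  spec <- cohort_spec(n_patients = 1, sds = c(
    alpha_angle = 0, lcea = 0, acetabular_version = 0, femoral_version = 0,
    head_radius = 0, neck_shaft_angle = 0), seed = 3)
  co <- sample_cohort(spec, resolution = 2.5, quiet = TRUE)
  p <- co$models[[1]]$params
  expect_equal(p$alpha_angle, 67.13, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(p$lcea, 30.77, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(abs(co$covariates$femoral_version - 14.19), 2)
})

test_that("infeasible parameters raise informative generation errors", {
  expect_error(anatomy_params(alpha_angle = 120), "alpha_angle")
  expect_error(anatomy_params(lcea = 70), "lcea")
  expect_error(anatomy_params(head_radius = -1), "head_radius")
  expect_error(generate_hip(anatomy_params(lcea = 1)), "infeasible|LCEA")
})
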