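test_that("posing is rigid, identity at zero, and composes about a fixed axis", {
  h <- mean_hip()
  f0 <- pose_femur(h, hip_posture(0, 0, 0))
  expect_equal(f0$vertices, h$femur$vertices, tolerance = 1e-12)

  f90 <- pose_femur(h, hip_posture(90, 0, 0))
  # two successive 45-degree flexions about the same fixed axis
  m45 <- h
  m45$femur <- pose_femur(h, hip_posture(45, 0, 0))
  f45x2 <- pose_femur(m45, hip_posture(45, 0, 0))
  expect_equal(f45x2$vertices, f90$vertices, tolerance = 1e-9)

  # head center fixed exactly; distances preserved
  expect_equal(f90$landmarks$head_center, h$femur$landmarks$head_center,
               tolerance = 1e-12)
  i <- c(1, 100, 1000)
  expect_equal(sqrt(rowSums(f90$vertices[i, ]^2)),
               sqrt(rowSums(h$femur$vertices[i, ]^2)), tolerance = 1e-9)
})

test_that("the posed frame matches the closed-form rotation product", {
  h <- mean_hip()
  post <- hip_posture(90, 0, 30)
  fm <- pose_femur(h, post)
  lat <- h$fpp$axes[, 2]; ant <- h$fpp$axes[, 1]
  dl <- (h$femur$landmarks$knee_center - h$femur$landmarks$head_center)
  dl <- dl / sqrt(sum(dl^2))
  Rx <- rotation_about(lat, -90) %*% rotation_about(ant, 0) %*%
    rotation_about(dl, -30)
  v0 <- h$femur$landmarks$medial_epicondyle - h$femur$landmarks$head_center
  expect_equal(fm$landmarks$medial_epicondyle,
               as.numeric(Rx %*% v0) + h$femur$landmarks$head_center,
               tolerance = 1e-9)
})

test_that("posture sign conventions follow the clinical definitions", {
  h <- mean_hip()
  knee0 <- h$femur$landmarks$knee_center
  expect_gt(pose_femur(h, hip_posture(30, 0, 0))$landmarks$knee_center[1],
            knee0[1])                       # flexion moves the knee anterior
  expect_gt(pose_femur(h, hip_posture(0, 15, 0))$landmarks$knee_center[2],
            knee0[2])                       # right-hip adduction -> medial (+Y)
  med0 <- h$femur$landmarks$medial_epicondyle
  med <- pose_femur(h, hip_posture(0, 0, 20))$landmarks$medial_epicondyle
  expect_lt(med[1], med0[1])                # internal rotation turns the
                                            # medial epicondyle posteriorly
})

test_that("sphere pairs collide exactly when overlapping", {
  sph <- function(c0, r = 1) {
    pm <- hipimpinge:::polar_mesh(function(U) rep(r, nrow(U)), c(0, 0, 1), 24, 24)
    bone_mesh(sweep(pm$vertices, 2, c0, `+`), pm$faces)
  }
  a <- sph(c(0, 0, 0))
  expect_false(detect_collision(a, sph(c(3, 0, 0)))$hit)
  d <- detect_collision(a, sph(c(1, 0, 0)))
  expect_true(d$hit)
  # contact centroid on the radical plane (x = 0.5 for unit spheres 1 apart)
  expect_lt(abs(d$contact_point[1] - 0.5), 0.02)
  # non-watertight input is rejected by name
  holed <- a; holed$faces <- holed$faces[-1, ]
  attr(holed, "watertight") <- NULL
  expect_error(detect_collision(holed, sph(c(1, 0, 0))), "pelvis")
})

test_that("limiting flexion against a plane matches the analytic tangency angle", {
  set.seed(12)
  tested <- 0
  cond <- list(id = 1, mode = "max_flexion", fixed_flexion = NA,
               fixed_adduction = 0, threshold = 130)
  while (tested < 6) {
    D <- runif(1, 40, 70); rho <- runif(1, 8, 16)
    L <- runif(1, D, 95); phi0 <- runif(1, 5, 30)
    if (L * sin(phi0 * pi / 180) + rho >= D - 2) next
    if ((D - rho) / L >= 0.93) next   # keep the tangency well-conditioned
    rig <- plate_femur_rig(D, rho, L, phi0)
    res <- max_angle_search(rig$model, cond)
    expect_lt(abs(res$limiting_angle - rig$theta_star), 0.2)
    tested <- tested + 1
  }
})

test_that("degenerate caps and baseline collisions are handled, not fatal", {
  h <- mean_hip()
  cond <- list(id = 4, mode = "max_internal_rotation", fixed_flexion = 90,
               fixed_adduction = 0, threshold = 30)
  r0 <- max_angle_search(h, cond, cap = 0)
  expect_equal(r0$limiting_angle, 0)
  expect_false(r0$impinged)

  # a plate already touching the neck at the start posture: flagged as a
  # baseline collision, recorded at 0 degrees, not an error
  rig <- plate_femur_rig(D = 45, rho = 12, L = 80, phi0 = 30)  # 80*sin30+12 > 45
  cond1 <- list(id = 1, mode = "max_flexion", fixed_flexion = NA,
                fixed_adduction = 0, threshold = 130)
  rb <- max_angle_search(rig$model, cond1)
  expect_equal(rb$limiting_angle, 0)
  expect_true(rb$impinged)
  expect_true(rb$baseline_collision)
  expect_false(is.null(rb$contact_point))
})

test_that("a no-cam hip clears internal rotation at 45 degrees flexion", {
  h <- nocam_hip()
  cond <- list(id = 10, mode = "max_internal_rotation", fixed_flexion = 45,
               fixed_adduction = 0, threshold = 30)
  res <- max_angle_search(h, cond, pelvic_pose(0))
  expect_false(res$impinged)
  expect_equal(res$limiting_angle, 30)
})

test_that("increasing cam severity never increases the limiting rotation", {
  lims <- sapply(c(50, 60, 70, 80), function(alpha) {
    h <- cached_hip(paste0("sev", alpha), anatomy_params(alpha_angle = alpha), 2.0)
    cond <- list(id = 4, mode = "max_internal_rotation", fixed_flexion = 90,
                 fixed_adduction = 0, threshold = 30)
    max_angle_search(h, cond, pelvic_pose(0))$limiting_angle
  })
  expect_true(all(diff(lims) <= 1e-9))
})

test_that("the protocol is structurally complete, deterministic and tilt-responsive", {
  h <- mean_hip()
  r1 <- run_protocol(h, 0)
  r2 <- run_protocol(h, 0)
  expect_identical(r1, r2)
  expect_equal(r1$condition_id, 1:12)
  expect_equal(nrow(r1), 12)
  expect_true(all(is.na(r1$region[!r1$impinged])))
  expect_true(all(r1$region[r1$impinged] %in% c("A", "B", "C")))

  # anterior tilt produces at least as many AIIS-region impingements
  ra <- run_protocol(h, -10)
  rp <- run_protocol(h, 10)
  nA <- function(r) sum(r$impinged & r$region == "A", na.rm = TRUE)
  expect_gte(nA(ra), nA(rp))
})

test_that("limiting angles are invariant under rigid motions of the whole hip", {
  h <- mean_hip()
  cond <- list(id = 5, mode = "max_internal_rotation", fixed_flexion = 90,
               fixed_adduction = 10, threshold = 30)
  r1 <- max_angle_search(h, cond, pelvic_pose(0))
  set.seed(3)
  R <- rotation_about(rnorm(3), 37)
  h2 <- hipimpinge:::transform_hip(h, R, t = c(12, -8, 5))
  r2 <- max_angle_search(h2, cond, pelvic_pose(0))
  expect_lt(abs(r1$limiting_angle - r2$limiting_angle), 0.1 + 1e-9)
})

test_that("mesh collision verdicts agree with the voxel-overlap oracle", {
  # smoke-scale version of the full oracle-equivalence study (the acceptance
  # suite runs 100 configurations over three hips)
  h <- mean_hip()
  ctx <- oracle_context(h, 0)
  set.seed(21)
  checked <- 0
  for (i in 1:10) {
    p <- hip_posture(runif(1, 0, 130), runif(1, -20, 20), runif(1, -30, 30))
    a <- oracle_agreement(ctx, p)
    if (!is.na(a)) { expect_true(a); checked <- checked + 1 }
  }
  expect_gte(checked, 5)
})
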