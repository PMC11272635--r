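#' Anatomical parameter set for one synthetic hip
#'
#' Bundles and validates the shape parameters of the parametric hip
#' generator. Angles in degrees, lengths in mm.
#'
#' @param alpha_angle head-neck asphericity (cam severity), in \[30, 100\].
#' @param lcea lateral center-edge angle (acetabular coverage), in \[0, 60\].
#' @param acetabular_version axial orientation of the acetabular opening
#'   (positive = anteverted).
#' @param femoral_version axial neck rotation relative to the epicondylar
#'   axis (positive = anteverted).
#' @param aiis_type Hetsroni AIIS morphotype, `"I"`, `"II"` or `"III"`:
#'   prominence above, at, or below the acetabular rim plane. The study
#'   cohort the defaults emulate contained no type III hips; type III is
#'   supported as an extrapolation.
#' @param head_radius femoral head radius, mm.
#' @param neck_shaft_angle femoral neck-shaft angle, degrees.
#' @param side `"right"` or `"left"`.
#' @return object of class `anatomy_params`.
#' @export
anatomy_params <- function(alpha_angle = 67.13, lcea = 30.77,
                           acetabular_version = 18.63, femoral_version = 14.19,
                           aiis_type = c("II", "I", "III"),
                           head_radius = 24, neck_shaft_angle = 128,
                           side = c("right", "left")) {
  aiis_type <- match.arg(aiis_type)
  side <- match.arg(side)
  stopifnot(is.numeric(alpha_angle), is.numeric(lcea), is.numeric(head_radius))
  if (alpha_angle < 30 || alpha_angle > 100)
    stop("alpha_angle must be in [30, 100] degrees", call. = FALSE)
  if (lcea < 0 || lcea > 60)
    stop("lcea must be in [0, 60] degrees", call. = FALSE)
  if (head_radius <= 0) stop("head_radius must be positive", call. = FALSE)
  structure(list(alpha_angle = alpha_angle, lcea = lcea,
                 acetabular_version = acetabular_version,
                 femoral_version = femoral_version, aiis_type = aiis_type,
                 head_radius = head_radius, neck_shaft_angle = neck_shaft_angle,
                 side = side),
            class = "anatomy_params")
}

#' @export
print.anatomy_params <- function(x, ...) {
  cat(sprintf(paste0("anatomy_params (%s hip): alpha %.1f, LCEA %.1f, ",
                     "AV %.1f, FV %.1f, AIIS type %s, head R %.1f mm\n"),
              x$side, x$alpha_angle, x$lcea, x$acetabular_version,
              x$femoral_version, x$aiis_type, x$head_radius))
  invisible(x)
}

# ---- polar meshing -----------------------------------------------------------

# Triangulate a sphere-topology polar grid: radial_fn(U) gives the radius for
# each unit direction; the polar axis is `axis` with reference directions
# (e1, e2) completing the frame. Returns vertices/faces (consistent winding,
# fixed to outward by signed volume).
polar_mesh <- function(radial_fn, axis, n_psi, n_beta) {
  axis <- unitv(axis)
  tmp <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(tmp - sum(tmp * axis) * axis)
  e2 <- pracma_cross(axis, e1)
  psi <- seq(0, pi, length.out = n_psi + 1)       # 0 = +axis pole
  beta <- seq(0, 2 * pi, length.out = n_beta + 1)[-(n_beta + 1)]
  rings <- psi[2:n_psi]
  U <- matrix(0, length(rings) * n_beta + 2, 3)
  U[1, ] <- axis
  idx <- 2
  for (p in rings) {
    dirs <- cos(p) * matrix(axis, n_beta, 3, byrow = TRUE) +
      sin(p) * (outer(cos(beta), e1) + outer(sin(beta), e2))
    U[idx:(idx + n_beta - 1), ] <- dirs
    idx <- idx + n_beta
  }
  U[idx, ] <- -axis
  r <- radial_fn(U)
  V <- U * r
  ring_start <- function(i) 2 + (i - 1) * n_beta   # i-th interior ring
  faces <- vector("list", n_psi)
  f1 <- cbind(1, ring_start(1) + (seq_len(n_beta) %% n_beta),
              ring_start(1) + seq_len(n_beta) - 1)
  faces[[1]] <- f1
  if (n_psi > 2) {
    for (i in 1:(n_psi - 2)) {
      a <- ring_start(i) + seq_len(n_beta) - 1
      b <- ring_start(i) + (seq_len(n_beta) %% n_beta)
      c2 <- ring_start(i + 1) + seq_len(n_beta) - 1
      d <- ring_start(i + 1) + (seq_len(n_beta) %% n_beta)
      faces[[i + 1]] <- rbind(cbind(a, b, c2), cbind(b, d, c2))
    }
  }
  last <- ring_start(n_psi - 1)
  fN <- cbind(nrow(U), last + seq_len(n_beta) - 1,
              last + (seq_len(n_beta) %% n_beta))
  faces[[n_psi]] <- fN
  F <- do.call(rbind, faces)
  vol <- sum(V[F[, 1], 1] * (V[F[, 2], 2] * V[F[, 3], 3] - V[F[, 2], 3] * V[F[, 3], 2]) -
             V[F[, 1], 2] * (V[F[, 2], 1] * V[F[, 3], 3] - V[F[, 2], 3] * V[F[, 3], 1]) +
             V[F[, 1], 3] * (V[F[, 2], 1] * V[F[, 3], 2] - V[F[, 2], 2] * V[F[, 3], 1])) / 6
  if (vol < 0) F <- F[, c(1, 3, 2)]
  list(vertices = V, faces = F, U = U)
}

# Two-sheet shell mesh for the pelvis plate: polar cap grids (gamma in
# [0, theta_dome]) for the inner and outer sheets, closed by a side wall.
shell_mesh <- function(ps, resolution) {
  axis <- ps$a_cup
  e1 <- ps$m1; e2 <- ps$m2
  gmax <- deg2rad(ps$theta_dome)
  r_typ <- ps$R_cup + ps$flare_amp / 2
  n_g <- max(16, ceiling(gmax * r_typ / resolution))
  n_b <- max(24, ceiling(2 * pi * r_typ / resolution))
  beta <- seq(0, 360, length.out = n_b + 1)[-(n_b + 1)]
  gam_edge <- deg2rad(ps$theta_cov + ps$band_at(beta))  # local dome edge
  dirs <- function(g) {              # g: per-azimuth polar angles (rad)
    cos(g) * matrix(axis, n_b, 3, byrow = TRUE) +
      sin(g) * (outer(cos(deg2rad(beta)), e1) + outer(sin(deg2rad(beta)), e2))
  }
  U <- matrix(0, n_g * n_b + 1, 3)
  U[1, ] <- axis
  for (i in seq_len(n_g))
    U[1 + (i - 1) * n_b + seq_len(n_b), ] <- dirs(gam_edge * i / n_g)
  sh <- pelvis_sheets(U, ps)
  Vin <- U * sh$r_in
  Vout <- U * sh$r_out
  nV <- nrow(U)
  V <- rbind(Vin, Vout)
  ring <- function(i) 1 + (i - 1) * n_b + seq_len(n_b)   # in U indexing
  cap_faces <- function(off, flip) {
    fs <- vector("list", n_g)
    r1 <- ring(1)
    fs[[1]] <- cbind(off + 1, off + r1[(seq_len(n_b) %% n_b) + 1], off + r1)
    if (n_g > 1) {
      for (i in 1:(n_g - 1)) {
        a <- off + ring(i); b <- off + ring(i)[(seq_len(n_b) %% n_b) + 1]
        c2 <- off + ring(i + 1); d <- off + ring(i + 1)[(seq_len(n_b) %% n_b) + 1]
        fs[[i + 1]] <- rbind(cbind(a, b, c2), cbind(b, d, c2))
      }
    }
    F <- do.call(rbind, fs)
    if (flip) F[, c(1, 3, 2)] else F
  }
  Fin <- cap_faces(0, flip = TRUE)        # inner sheet: normals toward joint
  Fout <- cap_faces(nV, flip = FALSE)     # outer sheet: normals outward
  # side wall between the two boundary rings
  bi <- ring(n_g); bo <- nV + ring(n_g)
  nb2 <- (seq_len(n_b) %% n_b) + 1
  Fwall <- rbind(cbind(bi[nb2], bi, bo), cbind(bi[nb2], bo, bo[nb2]))
  F <- rbind(Fin, Fout, Fwall)
  vol <- sum(V[F[, 1], 1] * (V[F[, 2], 2] * V[F[, 3], 3] - V[F[, 2], 3] * V[F[, 3], 2]) -
             V[F[, 1], 2] * (V[F[, 2], 1] * V[F[, 3], 3] - V[F[, 2], 3] * V[F[, 3], 1]) +
             V[F[, 1], 3] * (V[F[, 2], 1] * V[F[, 3], 2] - V[F[, 2], 2] * V[F[, 3], 1])) / 6
  if (vol < 0) F <- F[, c(1, 3, 2)]
  labels <- rep("bone", nrow(F))
  cen <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
  cup <- pelvis_cup_region(cen, ps) & seq_len(nrow(F)) <= nrow(Fin)
  labels[cup] <- "cup"
  list(vertices = V, faces = F, labels = labels)
}

# ---- hip model ---------------------------------------------------------------

#' Generate a synthetic hip model
#'
#' Builds watertight pelvis and femur surface meshes with embedded anatomical
#' landmarks from an [anatomy_params()] set. The hip is generated in a
#' canonical pose: acetabular center and femoral head center coincident at
#' the origin (a concentric ball-in-socket joint with 1 mm clearance), +X
#' anterior, +Y left, +Z cranial, functional pelvic plane axes aligned with
#' the global axes. Left hips are exact mirror images of the corresponding
#' right hip through the sagittal plane.
#'
#' The measured anatomy (alpha angle, LCEA, versions recomputed from the
#' output meshes and landmarks) is stored in `$measured` and agrees with the
#' request to within the generator contract of 2 degrees.
#'
#' @param params an [anatomy_params()] object.
#' @param resolution target mesh edge length in mm (default 1.5, echoing a
#'   1.5 mm CT slice thickness).
#' @return object of class `hip_model` with elements `pelvis`, `femur`
#'   (both [bone_mesh()]), `side`, `params`, `measured`, `rotation_center`,
#'   `cup` (cup axis/radius for joint-space masking), `tilt_deg`, and the
#'   analytic solids under `$internals`.
#' @export
generate_hip <- function(params, resolution = 1.5) {
  stopifnot(inherits(params, "anatomy_params"))
  k <- gen_constants()
  fs <- femur_solid(params$alpha_angle, params$femoral_version,
                    params$head_radius, params$neck_shaft_angle, k)
  ps <- pelvis_solid(params$lcea, params$acetabular_version,
                     params$head_radius, params$aiis_type, k)

  # femur mesh: polar grid about the neck axis
  r_typ <- 1.6 * fs$R
  n_psi <- max(24, ceiling(pi * r_typ / resolution))
  n_beta <- max(24, ceiling(2 * pi * fs$R / resolution))
  fm <- polar_mesh(function(U) femur_radial(U, fs), fs$a, n_psi, n_beta)

  femur_lm <- list(
    head_center = c(0, 0, 0),
    knee_center = c(0, 0, -k$knee_dist),
    medial_epicondyle = c(0, k$epi_halfw, -k$knee_dist),
    lateral_epicondyle = c(0, -k$epi_halfw, -k$knee_dist),
    neck_base = fs$P1,
    greater_trochanter_tip = fs$P1 + c(0, -0.5 * fs$R, 0.9 * fs$R),
    lesser_trochanter = fs$P1 + c(-8, 10, -25))
  # the spherical articular head surface sits 1 mm inside the cup at every
  # joint rotation and can never produce extra-articular contact; label it
  # so collision queries skip it (the cup surface is masked symmetrically)
  fr <- sqrt(rowSums(fm$vertices^2))
  fmaxr <- pmax(fr[fm$faces[, 1]], fr[fm$faces[, 2]], fr[fm$faces[, 3]])
  flab <- ifelse(fmaxr < fs$R + 0.5, "articular", "bone")
  femur <- bone_mesh(fm$vertices, fm$faces, femur_lm, face_labels = flab,
                     hints = list(side = if (params$side == "left") -1 else 1),
                     check = TRUE)

  # pelvis shell mesh
  pm <- shell_mesh(ps, resolution)
  rim_b <- deg2rad(seq(0, 360, length.out = 25)[-25])
  rim_u <- cos(deg2rad(ps$theta_cov)) * matrix(ps$a_cup, 24, 3, byrow = TRUE) +
    sin(deg2rad(ps$theta_cov)) * (outer(cos(rim_b), ps$m1) + outer(sin(rim_b), ps$m2))
  rim_pts <- rim_u * ps$R_cup
  sh_apex <- pelvis_sheets(matrix(ps$aiis$u_apex, 1), ps)
  apex_pt <- as.numeric(ps$aiis$u_apex * sh_apex$r_out)
  # inflection landmarks: azimuthal edges of the AIIS bump support
  dbeta <- ps$aiis$W / sin(deg2rad(ps$aiis$gamma_a))
  infl <- lapply(c(-1, 1), function(s) {
    b <- deg2rad(ps$aiis$beta_a + s * dbeta)
    u <- cos(deg2rad(ps$aiis$gamma_a)) * ps$a_cup +
      sin(deg2rad(ps$aiis$gamma_a)) * (cos(b) * ps$m1 + sin(b) * ps$m2)
    sh <- pelvis_sheets(matrix(u, 1), ps)
    as.numeric(u * sh$r_out)
  })
  if (infl[[1]][3] < infl[[2]][3]) infl <- rev(infl)  # first one is cranial
  pelvis_lm <- c(
    list(ASIS_right = c(k$asis_x, k$asis_y_same, k$asis_z),
         ASIS_left = c(k$asis_x, k$asis_y_contra, k$asis_z),
         pubic_midpoint = c(k$asis_x, (k$asis_y_same + k$asis_y_contra) / 2, -15),
         acetabular_center = c(0, 0, 0),
         AIIS_apex = apex_pt,
         inflection_ASIS_AIIS = infl[[1]],
         inflection_AIIS_rim = infl[[2]]),
    stats::setNames(lapply(seq_len(24), function(i) rim_pts[i, ]),
                    paste0("acetabular_rim_", seq_len(24))))
  pelvis <- bone_mesh(pm$vertices, pm$faces, pelvis_lm,
                      face_labels = pm$labels,
                      hints = list(ct_z = c(0, 0, 1),
                                   side = if (params$side == "left") -1 else 1),
                      check = TRUE)

  model <- structure(
    list(pelvis = pelvis, femur = femur, side = params$side, params = params,
         rotation_center = c(0, 0, 0), resolution = resolution,
         tilt_deg = 0,
         cup = list(axis = ps$a_cup, radius = ps$R_cup,
                    theta_cov = ps$theta_cov),
         internals = list(femur_solid = fs, pelvis_solid = ps,
                          pelvis_rot = diag(3), femur_rot = diag(3),
                          mirrored = params$side == "left")),
    class = "hip_model")

  if (params$side == "left") {
    model$pelvis <- mirror_mesh(model$pelvis)
    model$femur <- mirror_mesh(model$femur)
    model$cup$axis <- model$cup$axis * c(1, -1, 1)
  }
  model$fpp <- define_fpp(model$pelvis)
  model$femoral_frame <- define_femoral_frame(model$femur)
  model$measured <- measure_anatomy(model)
  model
}

#' @export
print.hip_model <- function(x, ...) {
  cat(sprintf("hip_model (%s hip, tilt %+.1f deg)\n", x$side, x$tilt_deg))
  cat(sprintf("  pelvis: %d faces | femur: %d faces | resolution %.2g mm\n",
              nrow(x$pelvis$faces), nrow(x$femur$faces), x$resolution))
  m <- x$measured
  if (!is.null(m))
    cat(sprintf("  measured: alpha %.1f, LCEA %.1f, AV %.1f, FV %.1f (deg)\n",
                m$alpha_angle, m$lcea, m$acetabular_version, m$femoral_version))
  invisible(x)
}

# ---- cohort sampling ---------------------------------------------------------

#' Cohort specification for synthetic hip sampling
#'
#' Defaults reproduce the measured anatomy distribution of the emulated
#' clinical cohort: femoral version ~ N(14.19, 10.84^2), acetabular version ~
#' N(18.63, 6.34^2), LCEA ~ N(30.77, 6.55^2), alpha angle ~ N(67.13, 8.89^2)
#' degrees, AIIS types I:II:III with probabilities 28/78, 50/78, 0.
#'
#' @param n_patients number of hips to draw (>= 1).
#' @param means,sds named numeric vectors of parameter means / SDs; names
#'   among `alpha_angle`, `lcea`, `acetabular_version`, `femoral_version`,
#'   `head_radius`, `neck_shaft_angle`.
#' @param aiis_prob probabilities for AIIS types I, II, III (sum to 1).
#' @param side hip side for all patients.
#' @param seed integer random seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 78,
                        means = c(alpha_angle = 67.13, lcea = 30.77,
                                  acetabular_version = 18.63,
                                  femoral_version = 14.19,
                                  head_radius = 24, neck_shaft_angle = 128),
                        sds = c(alpha_angle = 8.89, lcea = 6.55,
                                acetabular_version = 6.34,
                                femoral_version = 10.84,
                                head_radius = 1.5, neck_shaft_angle = 4),
                        aiis_prob = c(I = 28 / 78, II = 50 / 78, III = 0),
                        side = "right", seed = 1L) {
  stopifnot(n_patients >= 1)
  if (abs(sum(aiis_prob) - 1) > 1e-8)
    stop("aiis_prob must sum to 1", call. = FALSE)
  def <- eval(formals(cohort_spec)$means)
  defs <- eval(formals(cohort_spec)$sds)
  def[names(means)] <- means
  defs[names(sds)] <- sds
  structure(list(n_patients = as.integer(n_patients), means = def, sds = defs,
                 aiis_prob = aiis_prob, side = side, seed = as.integer(seed)),
            class = "cohort_spec")
}

# feasible parameter ranges used for clipping cohort draws
.param_clip <- list(alpha_angle = c(32, 98), lcea = c(5, 55),
                    acetabular_version = c(0, 40),
                    femoral_version = c(-15, 45),
                    head_radius = c(19, 30), neck_shaft_angle = c(115, 145))

#' Sample a cohort of synthetic hips
#'
#' Draws anatomy parameters from the cohort distributions (clipping to the
#' generator's feasible ranges, with clipping reported), generates each hip,
#' and returns the models with a covariate table carrying the *measured*
#' anatomy.
#'
#' @param spec a [cohort_spec()].
#' @param resolution mesh edge length in mm, passed to [generate_hip()].
#' @param quiet suppress the clipping message.
#' @return list with `models` (list of `hip_model`) and `covariates`
#'   (data.frame of patient_id, aiis_type and measured angles). The number of
#'   clipped draws is in `attr(, "n_clipped")` of the covariate table.
#' @export
sample_cohort <- function(spec, resolution = 1.5, quiet = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  models <- vector("list", spec$n_patients)
  cov <- vector("list", spec$n_patients)
  n_clipped <- 0L
  for (i in seq_len(spec$n_patients)) {
    model <- NULL
    for (try in seq_len(100)) {
      draw <- stats::rnorm(length(spec$means), spec$means, spec$sds)
      names(draw) <- names(spec$means)
      for (nm in names(draw)) {
        cl <- .param_clip[[nm]]
        if (draw[nm] < cl[1] || draw[nm] > cl[2]) {
          draw[nm] <- min(max(draw[nm], cl[1]), cl[2])
          n_clipped <- n_clipped + 1L
        }
      }
      at <- sample(c("I", "II", "III"), 1, prob = spec$aiis_prob)
      p <- anatomy_params(alpha_angle = draw["alpha_angle"],
                          lcea = draw["lcea"],
                          acetabular_version = draw["acetabular_version"],
                          femoral_version = draw["femoral_version"],
                          aiis_type = at, head_radius = draw["head_radius"],
                          neck_shaft_angle = draw["neck_shaft_angle"],
                          side = spec$side)
      model <- tryCatch(generate_hip(p, resolution = resolution),
                        error = function(e) NULL)
      if (!is.null(model)) break
    }
    if (is.null(model))
      stop("failed to generate patient ", i, " after 100 attempts", call. = FALSE)
    models[[i]] <- model
    m <- model$measured
    cov[[i]] <- data.frame(patient_id = i, aiis_type = model$params$aiis_type,
                           alpha_angle = m$alpha_angle, lcea = m$lcea,
                           acetabular_version = m$acetabular_version,
                           femoral_version = m$femoral_version,
                           head_radius = model$params$head_radius)
  }
  covariates <- do.call(rbind, cov)
  attr(covariates, "n_clipped") <- n_clipped
  if (!quiet && n_clipped > 0)
    message(n_clipped, " parameter draw(s) clipped to feasible ranges")
  list(models = models, covariates = covariates)
}
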