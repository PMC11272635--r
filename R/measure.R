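#' Radiographic-style measurements on hip meshes
#'
#' These operations recompute the anatomical parameters from the generated
#' (or user-supplied) meshes and landmarks, closing the loop on the
#' generator: `generate_hip()` guarantees the measured values agree with the
#' requested parameters to within 2 degrees.
#'
#' @name measurement
NULL

# Algebraic least-squares sphere fit. P: n x 3. Returns list(center, radius).
fit_sphere <- function(P) {
  P <- as.matrix(P)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  list(center = center, radius = radius)
}

#' Measure the alpha angle of a femur mesh
#'
#' Fits a sphere to the femoral head (vertices in the polar cap opposite the
#' neck), then finds where the head-neck surface first exits the fitted
#' sphere inflated by a 2% sphericity tolerance, scanning from the head pole
#' toward the neck. The alpha angle is the angle at the head center between
#' the neck axis and the ray to that exit point; the exit is located
#' sub-resolution by linear interpolation along mesh edges crossing the
#' tolerance sphere.
#'
#' @param model a `hip_model`, or a femur [bone_mesh()] with `head_center`
#'   and `neck_base` landmarks.
#' @return alpha angle in degrees.
#' @export
measure_alpha_angle <- function(model) {
  femur <- if (inherits(model, "hip_model")) model$femur else model
  lm <- femur$landmarks
  if (is.null(lm$head_center) || is.null(lm$neck_base))
    stop("femur needs head_center and neck_base landmarks", call. = FALSE)
  ax <- lm$neck_base - lm$head_center
  if (sqrt(sum(ax^2)) < 1e-6)
    stop("degenerate neck axis: neck_base coincides with head_center", call. = FALSE)
  a <- unitv(ax)
  V <- femur$vertices
  rel <- sweep(V, 2, lm$head_center)
  cpsi <- as.numeric(rel %*% a) / sqrt(rowSums(rel^2))
  cap <- cpsi < cos(deg2rad(110))            # polar cap, far from neck & cam
  if (sum(cap) < 20) stop("too few head vertices for a sphere fit", call. = FALSE)
  sp <- fit_sphere(V[cap, , drop = FALSE])
  thr <- 1.02 * sp$radius
  r <- sqrt(rowSums(sweep(V, 2, sp$center)^2))
  f <- femur$faces
  E <- unique(rbind(
    cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
    cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
    cbind(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3]))))
  r1 <- r[E[, 1]]; r2 <- r[E[, 2]]
  cross <- (r1 - thr) * (r2 - thr) < 0
  if (!any(cross)) stop("no exit from the head sphere found", call. = FALSE)
  Ec <- E[cross, , drop = FALSE]
  t <- (thr - r[Ec[, 1]]) / (r[Ec[, 2]] - r[Ec[, 1]])
  Px <- V[Ec[, 1], , drop = FALSE] * (1 - t) + V[Ec[, 2], , drop = FALSE] * t
  relx <- sweep(Px, 2, sp$center)
  psi <- rad2deg(acos(pmax(-1, pmin(1, as.numeric(relx %*% a) /
                                      sqrt(rowSums(relx^2))))))
  # alpha is read off the anterosuperior head-neck profile (where cam
  # deformities sit); the opposite azimuths would pick up the
  # intertrochanteric/shaft silhouette instead of the head-neck contour
  if (!is.null(lm$knee_center)) {
    l <- unitv(lm$head_center - lm$knee_center)
    n1 <- unitv(pracma_cross(a, -l))
    n2 <- pracma_cross(a, n1)
    if (sum(n2 * l) < 0) n2 <- -n2
    beta <- rad2deg(atan2(as.numeric(relx %*% n2), as.numeric(relx %*% n1)))
    dbeta <- abs(((beta - gen_constants()$cam_azimuth + 180) %% 360) - 180)
    if (any(dbeta <= 90)) psi <- psi[dbeta <= 90]
  }
  max(psi)
}

# Lateral direction of a model's pelvis frame (unit vector pointing toward
# the modeled side).
.lateral_dir <- function(frame, side) {
  if (side == "left") frame$axes[, 2] else -frame$axes[, 2]
}

#' Measure the lateral center-edge angle from the rim landmarks
#'
#' In the coronal projection of the pelvis frame, the LCEA is the angle from
#' the cranial axis to the ray from the acetabular center through the
#' lateral edge of the acetabular roof (the superolateral rim sample
#' subtending the smallest angle from vertical).
#'
#' @param model a `hip_model` (or a pelvis mesh plus `side`).
#' @param side hip side, defaulted from the model.
#' @return LCEA in degrees.
#' @export
measure_lcea <- function(model, side = NULL) {
  pelvis <- if (inherits(model, "hip_model")) model$pelvis else model
  if (is.null(side)) side <- if (inherits(model, "hip_model")) model$side else "right"
  check_landmarks(pelvis, c("acetabular_center"), rim_samples = TRUE)
  fr <- define_fpp(pelvis)
  lat <- .lateral_dir(fr, side)
  cran <- fr$axes[, 3]
  ctr <- pelvis$landmarks$acetabular_center
  rs <- sweep(rim_samples(pelvis), 2, ctr)
  U <- rs / sqrt(rowSums(rs^2))
  ul <- as.numeric(U %*% lat); uz <- as.numeric(U %*% cran)
  sel <- which(uz > 0)
  if (!length(sel)) stop("no superior rim samples found", call. = FALSE)
  i <- sel[which.max(ul[sel])]             # lateral edge of the roof
  rad2deg(atan2(ul[i], uz[i]))
}

#' Measure the acetabular version from the rim plane
#'
#' Fits a plane to the rim samples; the version is the angle between the
#' opening normal's transverse-plane projection and the lateral axis
#' (positive anterior).
#'
#' @inheritParams measure_lcea
#' @return acetabular version in degrees.
#' @export
measure_acetabular_version <- function(model, side = NULL) {
  pelvis <- if (inherits(model, "hip_model")) model$pelvis else model
  if (is.null(side)) side <- if (inherits(model, "hip_model")) model$side else "right"
  check_landmarks(pelvis, c("acetabular_center"), rim_samples = TRUE)
  fr <- define_fpp(pelvis)
  ctr <- pelvis$landmarks$acetabular_center
  rs <- rim_samples(pelvis)
  rel <- sweep(rs, 2, colMeans(rs))
  n <- svd(rel)$v[, 3]
  latd <- .lateral_dir(fr, side)
  if (sum(n * latd) < 0) n <- -n     # the opening always faces laterally
  ant <- sum(n * fr$axes[, 1])
  latc <- sum(n * latd)
  rad2deg(atan2(ant, latc))
}

#' Measure the femoral version from the landmarks
#'
#' Angle between the femoral neck axis (neck base to head center) and the
#' epicondylar axis, both projected on the plane orthogonal to the
#' mechanical (head-knee) axis; positive = anteversion.
#'
#' @param model a `hip_model` or femur [bone_mesh()].
#' @param side hip side, defaulted from the model.
#' @return femoral version in degrees.
#' @export
measure_femoral_version <- function(model, side = NULL) {
  femur <- if (inherits(model, "hip_model")) model$femur else model
  if (is.null(side)) side <- if (inherits(model, "hip_model")) model$side else "right"
  lm <- femur$landmarks
  check_landmarks(femur, c("head_center", "knee_center", "medial_epicondyle",
                           "lateral_epicondyle"))
  if (is.null(lm$neck_base)) stop("femur needs a neck_base landmark", call. = FALSE)
  l <- unitv(lm$head_center - lm$knee_center)
  v_neck <- lm$head_center - lm$neck_base
  m_ax <- lm$medial_epicondyle - lm$lateral_epicondyle
  s <- if (side == "left") 1 else -1
  s * signed_angle(m_ax, v_neck, l)
}

# All measurements bundled (used by generate_hip and sample_cohort).
measure_anatomy <- function(model) {
  list(alpha_angle = measure_alpha_angle(model),
       lcea = measure_lcea(model),
       acetabular_version = measure_acetabular_version(model),
       femoral_version = measure_femoral_version(model))
}
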