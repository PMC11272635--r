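#' Anatomical coordinate frames and pelvic tilt
#'
#' A `frame` is an origin plus a 3x3 orthonormal, right-handed axis matrix
#' whose columns are the anterior, left (the spec of the functional pelvic
#' plane makes the lateral axis point from the right to the left ASIS), and
#' cranial unit directions.
#'
#' @name frames
NULL

new_frame <- function(origin, axes) {
  axes <- as.matrix(axes)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9)
    stop("frame axes are not orthonormal", call. = FALSE)
  if (det(axes) < 0)
    stop("frame axes are not right-handed", call. = FALSE)
  structure(list(origin = as.numeric(origin), axes = axes), class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat("frame\n  origin:", sprintf("%.2f", x$origin), "\n")
  lab <- c("anterior", "left", "cranial")
  for (i in 1:3)
    cat(sprintf("  %-9s: % .4f % .4f % .4f\n", lab[i],
                x$axes[1, i], x$axes[2, i], x$axes[3, i]))
  invisible(x)
}

#' Functional pelvic plane frame
#'
#' Defines the functional pelvic plane (FPP) from the bilateral ASIS
#' landmarks and the CT table axis: the lateral axis runs from the right to
#' the left ASIS, the cranial axis is the CT Z direction orthogonalized
#' against it, and the anterior axis completes the right-handed triad. The
#' origin is the ASIS midpoint.
#'
#' The classic anterior pelvic plane (ASIS + pubic tubercles) is a different
#' convention; this package implements the ASIS + CT-Z definition used by
#' the simulation protocol. Supplying `ct_z` overrides the mesh's stored CT
#' axis hint.
#'
#' @param pelvis a pelvis [bone_mesh()] with `ASIS_left`/`ASIS_right`
#'   landmarks (plus `pubic_midpoint` for the APP variant).
#' @param ct_z CT axial direction (default: the mesh's `ct_z` hint, else
#'   global +Z).
#' @param variant `"fpp"` (default, ASIS + CT Z) or `"app"` (the classic
#'   anterior pelvic plane through both ASIS and the pubic midpoint).
#' @return a `frame`.
#' @export
define_fpp <- function(pelvis, ct_z = NULL, variant = c("fpp", "app")) {
  variant <- match.arg(variant)
  check_landmarks(pelvis, c("ASIS_left", "ASIS_right"))
  L <- pelvis$landmarks$ASIS_left
  R <- pelvis$landmarks$ASIS_right
  d <- L - R
  if (sqrt(sum(d^2)) < 1e-6)
    stop("ASIS landmarks are coincident", call. = FALSE)
  lat <- unitv(d)
  if (variant == "app") {
    check_landmarks(pelvis, "pubic_midpoint")
    v <- pelvis$landmarks$pubic_midpoint - (L + R) / 2
    ant <- v - sum(v * lat) * lat
    if (sqrt(sum(ant^2)) < 1e-6)
      stop("pubic midpoint lies on the ASIS line", call. = FALSE)
    ant <- unitv(pracma_cross(lat, unitv(-ant)))   # plane normal, anterior
    cran <- pracma_cross(ant, lat)
    return(new_frame((L + R) / 2, cbind(ant, lat, cran)))
  }
  if (is.null(ct_z)) ct_z <- pelvis$hints$ct_z
  if (is.null(ct_z)) ct_z <- c(0, 0, 1)
  cz <- ct_z - sum(ct_z * lat) * lat
  if (sqrt(sum(cz^2)) < 1e-6)
    stop("CT Z axis is parallel to the ASIS line", call. = FALSE)
  cran <- unitv(cz)
  ant <- pracma_cross(lat, cran)
  new_frame((L + R) / 2, cbind(ant, lat, cran))
}

#' Femoral coordinate frame
#'
#' Origin at the femoral head center; cranial axis along the mechanical
#' (head-to-knee) axis; the flexion reference axis is the epicondylar line
#' (pointing left) orthogonalized against the long axis; anterior completes
#' the triad.
#'
#' @param femur a femur [bone_mesh()] with head/knee/epicondyle landmarks.
#' @param side `"right"` or `"left"`; default read from the mesh `side` hint.
#' @return a `frame`.
#' @export
define_femoral_frame <- function(femur, side = NULL) {
  check_landmarks(femur, c("head_center", "knee_center",
                           "medial_epicondyle", "lateral_epicondyle"))
  if (is.null(side))
    side <- if (identical(femur$hints$side, -1)) "left" else "right"
  h <- femur$landmarks$head_center
  kn <- femur$landmarks$knee_center
  if (sqrt(sum((h - kn)^2)) < 1e-6)
    stop("head_center and knee_center coincide", call. = FALSE)
  long <- unitv(h - kn)
  epi <- femur$landmarks$medial_epicondyle - femur$landmarks$lateral_epicondyle
  if (side == "left") epi <- -epi            # keep the axis pointing left
  left <- epi - sum(epi * long) * long
  left <- unitv(left)
  ant <- pracma_cross(left, long)
  new_frame(h, cbind(ant, left, long))
}

#' Pelvic pose (sagittal tilt)
#'
#' Sign convention: positive `tilt_deg` is posterior pelvic tilt (the ASIS
#' pair rotates posteriorly), negative is anterior tilt. The simulation
#' protocol evaluates -10, 0, +10 degrees.
#'
#' @param tilt_deg tilt in degrees, within \[-30, 30\].
#' @return object of class `pelvic_pose`.
#' @export
pelvic_pose <- function(tilt_deg = 0) {
  stopifnot(is.numeric(tilt_deg), length(tilt_deg) == 1)
  if (abs(tilt_deg) > 30)
    stop("tilt_deg outside the supported [-30, 30] degree range", call. = FALSE)
  structure(list(tilt_deg = tilt_deg), class = "pelvic_pose")
}

#' Apply pelvic tilt to a hip model
#'
#' Rotates the pelvis (mesh and landmarks) by the pose's tilt about the FPP
#' lateral axis passing through the hip rotation center (femoral head
#' center), so the joint center is invariant and only the relative
#' orientation changes. The femur is untouched. Pure: returns a new model.
#'
#' @param model a `hip_model`.
#' @param pose a [pelvic_pose()] or a tilt angle in degrees.
#' @return the tilted `hip_model` (with `tilt_deg` updated and frames
#'   recomputed).
#' @export
apply_pelvic_tilt <- function(model, pose) {
  if (is.numeric(pose)) pose <- pelvic_pose(pose)
  stopifnot(inherits(model, "hip_model"), inherits(pose, "pelvic_pose"))
  tau <- pose$tilt_deg
  if (tau == 0) return(model)
  lat <- model$fpp$axes[, 2]
  R <- rotation_about(lat, -tau)     # +tau posterior: ASIS move posteriorly
  out <- model
  out$pelvis <- transform_mesh(model$pelvis, R, center = model$rotation_center)
  out$cup$axis <- as.numeric(R %*% model$cup$axis)
  out$internals$pelvis_rot <- R %*% model$internals$pelvis_rot
  out$fpp <- define_fpp(out$pelvis)
  out$tilt_deg <- model$tilt_deg + tau
  out
}

# Rigidly transform a whole hip model (both bones, frames, bookkeeping).
# Used for rigid-motion invariance checks and user-space repositioning.
transform_hip <- function(model, R = diag(3), t = c(0, 0, 0)) {
  out <- model
  out$pelvis <- transform_mesh(model$pelvis, R, t)
  out$femur <- transform_mesh(model$femur, R, t)
  out$rotation_center <- as.numeric(R %*% model$rotation_center) + t
  out$cup$axis <- as.numeric(R %*% model$cup$axis)
  out$internals$pelvis_rot <- R %*% model$internals$pelvis_rot
  out$internals$femur_rot <- R %*% model$internals$femur_rot
  out$fpp <- define_fpp(out$pelvis)
  out$femoral_frame <- define_femoral_frame(out$femur)
  out
}
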