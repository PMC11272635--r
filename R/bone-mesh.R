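#' Bone surface mesh with anatomical landmarks
#'
#' A `bone_mesh` is a watertight triangle surface (vertices in mm, a
#' right-handed coordinate system with +X anterior, +Y left, +Z cranial)
#' together with a named list of anatomical landmark points. Landmarks need
#' not lie on the surface: virtual points (e.g. the knee center of a femur
#' meshed only proximally) are carried along and transformed rigidly with the
#' mesh. Optional per-face labels mark special surface regions (the
#' acetabular cup, used for joint-space masking during collision detection).
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented (outward normals, counter-clockwise seen from outside).
#' @param landmarks named list of numeric length-3 points.
#' @param face_labels optional character vector of length m (e.g. `"cup"`);
#'   default `"bone"` everywhere.
#' @param hints named list of direction hints attached to the bone and rotated
#'   with it; `ct_z` (the CT table axis) is set for generated pelves.
#' @param check if `TRUE` (default) validate watertightness.
#' @return object of class `bone_mesh`.
#' @export
bone_mesh <- function(vertices, faces, landmarks = list(), face_labels = NULL,
                      hints = list(), check = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (is.null(face_labels)) face_labels <- rep("bone", nrow(faces))
  m <- structure(
    list(vertices = vertices, faces = faces, landmarks = landmarks,
         face_labels = face_labels, hints = hints),
    class = "bone_mesh")
  if (check) {
    wt <- is_watertight(m)
    if (!isTRUE(wt)) stop("mesh is not watertight: ", attr(wt, "why"), call. = FALSE)
    attr(m, "watertight") <- TRUE
  }
  m
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf("bone_mesh: %d vertices, %d faces, %d landmarks\n",
              nrow(x$vertices), nrow(x$faces), length(x$landmarks)))
  if (length(x$landmarks))
    cat("  landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  invisible(x)
}

#' Check that a triangle mesh is watertight
#'
#' Every undirected edge must be shared by exactly two faces, traversed in
#' opposite directions (consistent orientation), and faces must be
#' non-degenerate.
#'
#' @param mesh a `bone_mesh` or a list with `vertices`/`faces`.
#' @return `TRUE`, or `FALSE` with a `why` attribute.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    return(structure(FALSE, why = "degenerate face (repeated vertex index)"))
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])  # directed half-edges
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key))
    return(structure(FALSE, why = "duplicated directed edge (inconsistent orientation or non-manifold)"))
  rkey <- paste(he[, 2], he[, 1])
  if (!all(rkey %in% key))
    return(structure(FALSE, why = "boundary edge (hole in surface)"))
  TRUE
}

#' Apply a rigid transform to a bone mesh
#'
#' Rotates by `R` about `center` then translates by `t`. Landmarks and
#' direction hints move with the mesh.
#'
#' @param mesh a `bone_mesh`.
#' @param R 3x3 rotation matrix.
#' @param t translation (length 3).
#' @param center rotation center (length 3).
#' @return transformed `bone_mesh`.
#' @export
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0), center = c(0, 0, 0)) {
  mv <- sweep(sweep(mesh$vertices, 2, center) %*% t(R), 2, center + t, `+`)
  lm <- lapply(mesh$landmarks, function(p) as.numeric(R %*% (p - center)) + center + t)
  hi <- lapply(mesh$hints, function(v)
    if (is.numeric(v) && length(v) == 3) as.numeric(R %*% v) else v)
  out <- mesh
  out$vertices <- mv
  out$landmarks <- lm
  out$hints <- hi
  out
}

#' Mirror a bone mesh through a sagittal plane
#'
#' Reflects through the plane y = `y0` (the package's sagittal plane normal is
#' +Y). Face winding is flipped to keep outward orientation, and left/right
#' landmark names (`ASIS_left`/`ASIS_right`) are swapped.
#'
#' @param mesh a `bone_mesh`.
#' @param y0 plane offset along Y (default 0).
#' @return mirrored `bone_mesh`.
#' @export
mirror_mesh <- function(mesh, y0 = 0) {
  v <- mesh$vertices
  v[, 2] <- 2 * y0 - v[, 2]
  f <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  lm <- lapply(mesh$landmarks, function(p) { p[2] <- 2 * y0 - p[2]; p })
  nm <- names(lm)
  nm[nm == "ASIS_left"] <- ".tmp"
  nm[nm == "ASIS_right"] <- "ASIS_left"
  nm[nm == ".tmp"] <- "ASIS_right"
  names(lm) <- nm
  hi <- lapply(mesh$hints, function(d) {
    if (is.numeric(d) && length(d) == 3) d[2] <- -d[2]
    d
  })
  out <- mesh
  out$vertices <- v
  out$faces <- f
  out$landmarks <- lm
  out$hints <- hi
  out
}

required_pelvis_landmarks <- c("ASIS_left", "ASIS_right", "acetabular_center",
                               "AIIS_apex", "inflection_ASIS_AIIS",
                               "inflection_AIIS_rim")
required_femur_landmarks <- c("head_center", "knee_center", "medial_epicondyle",
                              "lateral_epicondyle", "greater_trochanter_tip",
                              "lesser_trochanter")

check_landmarks <- function(mesh, required, rim_samples = FALSE) {
  missing <- setdiff(required, names(mesh$landmarks))
  if (length(missing))
    stop("missing landmarks: ", paste(missing, collapse = ", "), call. = FALSE)
  if (rim_samples) {
    rs <- mesh$landmarks[grepl("^acetabular_rim_", names(mesh$landmarks))]
    if (length(rs) < 12)
      stop("need >= 12 acetabular_rim_* landmark samples", call. = FALSE)
  }
  invisible(TRUE)
}

# Collect the rim ring samples as a k x 3 matrix, ordered by index suffix.
rim_samples <- function(pelvis) {
  nm <- names(pelvis$landmarks)
  rs <- nm[grepl("^acetabular_rim_", nm)]
  rs <- rs[order(as.integer(sub("^acetabular_rim_", "", rs)))]
  do.call(rbind, pelvis$landmarks[rs])
}
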