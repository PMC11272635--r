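#' Range-of-motion engine: posing, collision, limiting angles
#'
#' The femur is posed about the fixed rotation center (femoral head center)
#' by the clinical intrinsic sequence: flexion about the (tilted) pelvic
#' medio-lateral axis, then adduction about the floating anteroposterior
#' axis, then internal rotation about the femoral long axis. Bone-on-bone
#' impingement is any extra-articular mesh intersection: contacts on the
#' articular cup surface (the congruent ball-in-socket interface) are
#' excluded via the cup face labels.
#'
#' @name rom_engine
NULL

#' Hip posture (flexion / adduction / internal rotation)
#'
#' @param flexion degrees, in \[0, 150\].
#' @param adduction degrees, in \[-30, 30\].
#' @param internal_rotation degrees, in \[-60, 60\].
#' @return object of class `hip_posture`.
#' @export
hip_posture <- function(flexion = 0, adduction = 0, internal_rotation = 0) {
  if (flexion < 0 || flexion > 150) stop("flexion outside [0, 150]", call. = FALSE)
  if (abs(adduction) > 30) stop("adduction outside [-30, 30]", call. = FALSE)
  if (abs(internal_rotation) > 60)
    stop("internal_rotation outside [-60, 60]", call. = FALSE)
  structure(list(flexion = flexion, adduction = adduction,
                 internal_rotation = internal_rotation),
            class = "hip_posture")
}

# Net pose rotation matrix for a posture (axes in current-model coordinates;
# intrinsic sequence expressed as a product of fixed-axis rotations).
pose_rotation <- function(model, posture) {
  s <- if (model$side == "left") -1 else 1
  lat <- model$fpp$axes[, 2]                 # tilted pelvic lateral (left)
  ant <- model$fpp$axes[, 1]
  lm <- model$femur$landmarks
  d_long <- unitv(lm$knee_center - lm$head_center)   # distal femoral axis
  R_flex <- rotation_about(lat, -posture$flexion)
  R_add <- rotation_about(ant, s * posture$adduction)
  R_ir <- rotation_about(d_long, -s * posture$internal_rotation)
  R_flex %*% R_add %*% R_ir
}

#' Pose the femur of a hip model
#'
#' Rotates the femur mesh about the head center through the given posture;
#' the transform is rigid and leaves the head center exactly fixed.
#'
#' @param model a `hip_model` (tilt already applied if desired).
#' @param posture a [hip_posture()].
#' @return the posed femur [bone_mesh()].
#' @export
pose_femur <- function(model, posture) {
  stopifnot(inherits(model, "hip_model"), inherits(posture, "hip_posture"))
  R <- pose_rotation(model, posture)
  transform_mesh(model$femur, R, center = model$femur$landmarks$head_center)
}

#' Detect bone-to-bone collision between pelvis and femur meshes
#'
#' Surfaces intersecting anywhere outside the articular mask count as
#' collision. Contact points are the length-weighted centroids of the
#' intersection segments on the pelvis surface, grouped into connected
#' patches; the largest patch defines the reported contact point.
#'
#' @param pelvis pelvis [bone_mesh()] (faces labeled `"cup"` are excluded).
#' @param femur femur [bone_mesh()] in its posed position.
#' @param details if `TRUE`, compute contact points; otherwise only the
#'   verdict (faster).
#' @return list with `hit` (logical), and when `details` and hit:
#'   `contact_point` (on the pelvis surface), `n_patches`, `patch_lengths`.
#' @export
detect_collision <- function(pelvis, femur, details = TRUE) {
  for (nm in c("pelvis", "femur")) {
    msh <- get(nm)
    if (is.null(attr(msh, "watertight"))) {
      wt <- is_watertight(msh)
      if (!isTRUE(wt))
        stop("mesh '", nm, "' is not watertight: ", attr(wt, "why"), call. = FALSE)
    }
  }
  ctx <- collision_context(pelvis)
  ff <- femur$faces
  if (any(femur$face_labels == "articular"))
    ff <- ff[femur$face_labels != "articular", , drop = FALSE]
  res <- cpp_collide(ctx$ptr, femur$vertices, ff, !details)
  if (!details || !res$hit) return(list(hit = res$hit))
  c(list(hit = TRUE), contact_from_pairs(pelvis, ctx, res))
}

# Build (and cache on the mesh, via environment) the broadphase structure
# over the non-articular pelvis faces.
collision_context <- function(pelvis) {
  env <- attr(pelvis, "collision_env")
  if (!is.null(env) && !is.null(env$ptr)) return(env)
  keep <- which(pelvis$face_labels != "cup")
  env <- new.env(parent = emptyenv())
  env$keep <- keep
  env$ptr <- cpp_collision_prepare(pelvis$vertices,
                                   pelvis$faces[keep, , drop = FALSE])
  env
}

# Cache the context inside the model so repeated searches reuse it.
prepare_model_collision <- function(model) {
  ctx <- collision_context(model$pelvis)
  attr(model$pelvis, "collision_env") <- ctx
  model
}

# Contact extraction: group intersected pelvis faces into patches by shared
# vertices (union-find), pick the largest patch by intersection length.
contact_from_pairs <- function(pelvis, ctx, res) {
  pr <- res$pairs
  segs <- res$segments
  pf <- ctx$keep[pr[, 1]]                      # original pelvis face ids
  upf <- unique(pf)
  fidx <- match(pf, upf)
  parent <- seq_along(upf)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  fv <- pelvis$faces[upf, , drop = FALSE]
  vert_owner <- new.env(parent = emptyenv(), size = 4 * length(upf))
  for (i in seq_along(upf)) {
    for (v in fv[i, ]) {
      key <- as.character(v)
      j <- vert_owner[[key]]
      if (is.null(j)) assign(key, i, envir = vert_owner)
      else { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
    }
  }
  comp <- vapply(seq_along(upf), find, integer(1))
  len <- sqrt(rowSums((segs[, 1:3, drop = FALSE] - segs[, 4:6, drop = FALSE])^2))
  mid <- (segs[, 1:3, drop = FALSE] + segs[, 4:6, drop = FALSE]) / 2
  seg_comp <- comp[fidx]
  patch_len <- tapply(len, seg_comp, sum)
  main <- as.integer(names(patch_len)[which.max(patch_len)])
  sel <- seg_comp == main
  w <- len[sel]
  if (sum(w) < 1e-12) w <- rep(1, sum(sel))
  cp <- colSums(mid[sel, , drop = FALSE] * w) / sum(w)
  list(contact_point = as.numeric(cp), n_patches = length(patch_len),
       patch_lengths = as.numeric(patch_len))
}

#' The 12-condition activity-of-daily-living protocol
#'
#' Three maximum-flexion conditions (threshold 130 deg, adduction 0/10/20)
#' and nine maximum-internal-rotation conditions (threshold 30 deg, flexion
#' 90/70/45 crossed with adduction 0/10/20).
#'
#' @return data.frame with columns `id`, `mode`, `fixed_flexion`,
#'   `fixed_adduction`, `threshold`.
#' @export
protocol_conditions <- function() {
  data.frame(
    id = 1:12,
    mode = c(rep("max_flexion", 3), rep("max_internal_rotation", 9)),
    fixed_flexion = c(NA, NA, NA, 90, 90, 90, 70, 70, 70, 45, 45, 45),
    fixed_adduction = c(0, 10, 20, 0, 10, 20, 0, 10, 20, 0, 10, 20),
    threshold = c(130, 130, 130, rep(30, 9)),
    stringsAsFactors = FALSE)
}

.posture_at <- function(cond, angle) {
  if (cond$mode == "max_flexion")
    hip_posture(angle, cond$fixed_adduction, 0)
  else
    hip_posture(cond$fixed_flexion, cond$fixed_adduction, angle)
}

#' Find the maximal collision-free angle along a protocol sweep
#'
#' Sweeps the condition's free variable (flexion or internal rotation) from
#' zero in 1 degree steps up to the ADL threshold; on first collision,
#' bisects to 0.1 degree. The limiting angle is the largest collision-free
#' value; if no collision occurs by the threshold the condition does not
#' impinge and the limiting angle equals the cap.
#'
#' @param model a `hip_model`.
#' @param condition one row of [protocol_conditions()] (or a list with the
#'   same fields).
#' @param pose a [pelvic_pose()] applied before the search (default:
#'   model as-is).
#' @param cap search cap in degrees; defaults to the condition threshold.
#' @return list (`contact_result`): `limiting_angle`, `impinged`,
#'   `contact_point` (or `NULL`), `region` is filled by [run_protocol()],
#'   `baseline_collision` flag, `n_patches`.
#' @export
max_angle_search <- function(model, condition, pose = NULL, cap = NULL) {
  if (!is.null(pose)) model <- apply_pelvic_tilt(model, pose)
  model <- prepare_model_collision(model)
  if (is.null(cap)) cap <- condition$threshold
  collides <- function(angle) {
    fm <- pose_femur(model, .posture_at(condition, angle))
    detect_collision(model$pelvis, fm, details = FALSE)$hit
  }
  if (cap <= 0)
    return(structure(list(limiting_angle = 0, impinged = FALSE,
                          contact_point = NULL, baseline_collision = FALSE,
                          n_patches = 0L), class = "contact_result"))
  if (collides(0)) {
    fm <- pose_femur(model, .posture_at(condition, 0))
    det <- detect_collision(model$pelvis, fm, details = TRUE)
    return(structure(list(limiting_angle = 0, impinged = TRUE,
                          contact_point = det$contact_point,
                          baseline_collision = TRUE,
                          n_patches = det$n_patches), class = "contact_result"))
  }
  lo <- 0; hi <- NA
  for (ang in seq_len(floor(cap))) {
    if (collides(ang)) { hi <- ang; break }
    lo <- ang
  }
  if (is.na(hi)) {                             # check the (possibly
    if (cap > lo && collides(cap)) hi <- cap   # non-integer) cap itself
    else
      return(structure(list(limiting_angle = cap, impinged = FALSE,
                            contact_point = NULL, baseline_collision = FALSE,
                            n_patches = 0L), class = "contact_result"))
  }
  while (hi - lo > 0.1) {
    mid <- (hi + lo) / 2
    if (collides(mid)) hi <- mid else lo <- mid
  }
  fm <- pose_femur(model, .posture_at(condition, hi))
  det <- detect_collision(model$pelvis, fm, details = TRUE)
  structure(list(limiting_angle = lo, impinged = lo < condition$threshold,
                 contact_point = det$contact_point, baseline_collision = FALSE,
                 n_patches = if (isTRUE(det$hit)) det$n_patches else 0L),
            class = "contact_result")
}

#' Run the 12-condition protocol on one hip at one pelvic pose
#'
#' Applies the pelvic tilt, runs [max_angle_search()] for each protocol
#' condition, and classifies each contact point into acetabular regions A
#' (AIIS/subspine), B (anterior) or C (posterolateral).
#'
#' @param model a `hip_model`.
#' @param pose a [pelvic_pose()] or numeric tilt in degrees.
#' @param patient_id identifier copied into the records.
#' @return data.frame of 12 impingement records: `patient_id`, `tilt_deg`,
#'   `condition_id`, `mode`, `limiting_angle`, `impinged`, `region`,
#'   `contact_x/y/z`, `baseline_collision`, `n_patches`.
#' @export
run_protocol <- function(model, pose = 0, patient_id = 1L) {
  if (is.numeric(pose)) pose <- pelvic_pose(pose)
  tilted <- apply_pelvic_tilt(model, pose)
  tilted <- prepare_model_collision(tilted)
  sectors <- build_sectors(tilted$pelvis, tilted$fpp, side = tilted$side)
  conds <- protocol_conditions()
  rows <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cond <- as.list(conds[i, ])
    cr <- max_angle_search(tilted, cond)
    region <- NA_character_
    cp <- c(NA_real_, NA_real_, NA_real_)
    if (cr$impinged && !is.null(cr$contact_point)) {
      region <- classify_contact(cr$contact_point, sectors)
      cp <- cr$contact_point
    }
    rows[[i]] <- data.frame(
      patient_id = patient_id, tilt_deg = pose$tilt_deg,
      condition_id = cond$id, mode = cond$mode,
      limiting_angle = cr$limiting_angle, impinged = cr$impinged,
      region = region, contact_x = cp[1], contact_y = cp[2],
      contact_z = cp[3], baseline_collision = cr$baseline_collision,
      n_patches = cr$n_patches, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
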