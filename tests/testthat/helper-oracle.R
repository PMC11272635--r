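# Voxel-overlap collision oracle, independent of the triangle-intersection
# path: both bones are exact analytic solids (radial functions), so point
# membership is evaluated directly on a 0.5 mm voxel grid. A configuration
# is "ambiguous" when eroding/inflating both solids by 0.25 mm flips the
# verdict (surfaces within ~0.5 mm of touching); outside that band the mesh
# route must agree.

oracle_context <- function(model, tilt, step = 0.5, margin = 0.25) {
  tilted <- apply_pelvic_tilt(model, pelvic_pose(tilt))
  ps <- model$internals$pelvis_solid
  Rp <- tilted$internals$pelvis_rot
  V <- tilted$pelvis$vertices
  lo <- apply(V, 2, min) - 2 * margin
  hi <- apply(V, 2, max) + 2 * margin
  xs <- seq(lo[1] + step / 2, hi[1], by = step)
  ys <- seq(lo[2] + step / 2, hi[2], by = step)
  zs <- seq(lo[3] + step / 2, hi[3], by = step)
  offs <- c(-margin, 0, margin)
  centers <- vector("list", 3)          # global coords per offset
  for (zi in seq_along(zs)) {
    slab <- cbind(rep(xs, times = length(ys)),
                  rep(ys, each = length(xs)), zs[zi])
    PL <- slab %*% Rp                   # pelvis-local coordinates
    cup <- hipimpinge:::pelvis_cup_region(PL, ps)
    for (oi in 1:3) {
      ins <- hipimpinge:::pelvis_inside(PL, ps, offs[oi]) & !cup
      if (any(ins))
        centers[[oi]] <- c(centers[[oi]], list(slab[ins, , drop = FALSE]))
    }
  }
  list(tilted = tilted,
       centers = lapply(centers, function(l)
         if (length(l)) do.call(rbind, l) else matrix(0, 0, 3)),
       offs = offs, fs = model$internals$femur_solid)
}

# TRUE if any pelvis voxel (at offset index oi) is inside the posed femur
# solid at the matching offset.
oracle_hit <- function(ctx, posture, oi) {
  P <- ctx$centers[[oi]]
  if (!nrow(P)) return(FALSE)
  Rpose <- hipimpinge:::pose_rotation(ctx$tilted, posture)
  P0 <- P %*% Rpose                     # femur-local coordinates
  off <- ctx$offs[oi]
  chunk <- 100000L
  for (s in seq(1, nrow(P0), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(P0))
    if (any(hipimpinge:::femur_inside(P0[s:e, , drop = FALSE], ctx$fs, off)))
      return(TRUE)
  }
  FALSE
}

# Compare the mesh-intersection verdict with the oracle for one posture.
# Returns NA for ambiguous cases, otherwise TRUE iff the two routes agree.
oracle_agreement <- function(ctx, posture) {
  v_lo <- oracle_hit(ctx, posture, 1)   # eroded
  v_hi <- oracle_hit(ctx, posture, 3)   # inflated
  if (v_lo != v_hi) return(NA)
  fm <- pose_femur(ctx$tilted, posture)
  mesh_v <- detect_collision(ctx$tilted$pelvis, fm, details = FALSE)$hit
  identical(mesh_v, v_lo)
}

# ---- analytic capsule-vs-plane rig ------------------------------------------

# A hand-built "hip": the pelvis is a thin plate with inward normal -X at
# x = D, the femur a head sphere (radius R) plus a neck capsule of radius
# rho along direction a0 (unit, in the XZ plane, pointing inferior).
# Flexion (about the pelvic lateral axis +Y) rotates the capsule tip toward
# the plate; the first contact angle has the closed form
#   theta* = acos((D - rho) / L) - atan2(a0_x, -a0_z) ... derived below.
plate_femur_rig <- function(D, rho, L, phi0_deg, R = 20) {
  stopifnot(D > R + rho, D - rho < L)
  plate_v <- as.matrix(expand.grid(x = c(D, D + 6), y = c(-90, 90),
                                   z = c(-90, 90)))[, c("x", "y", "z")]
  # explicit box triangulation (12 faces, outward winding)
  f <- rbind(c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7))
  plate <- bone_mesh(plate_v, f,
                     landmarks = list(ASIS_right = c(0, -100, 120),
                                      ASIS_left = c(0, 100, 120)),
                     hints = list(ct_z = c(0, 0, 1)), check = TRUE)
  phi0 <- phi0_deg * pi / 180
  a0 <- c(sin(phi0), 0, -cos(phi0))     # capsule direction at zero flexion
  radial <- function(U) {
    r <- rep(R, nrow(U))
    pmax(r, hipimpinge:::.capsule_exit(U, c(0, 0, 0), L * a0, rho))
  }
  fm <- hipimpinge:::polar_mesh(radial, a0, 96, 120)
  femur <- bone_mesh(fm$vertices, fm$faces,
                     landmarks = list(head_center = c(0, 0, 0),
                                      knee_center = c(0, 0, -400),
                                      medial_epicondyle = c(0, 40, -400),
                                      lateral_epicondyle = c(0, -40, -400)),
                     hints = list(side = 1), check = TRUE)
  model <- structure(list(pelvis = plate, femur = femur, side = "right",
                          rotation_center = c(0, 0, 0), tilt_deg = 0,
                          resolution = 2), class = "hip_model")
  model$fpp <- define_fpp(plate)
  model$femoral_frame <- define_femoral_frame(femur)
  # flexion by theta maps a0 = (sin phi0, 0, -cos phi0) to
  # (sin(phi0 + theta), 0, -cos(phi0 + theta)); tip-x = L sin(phi0 + theta);
  # contact when L sin(phi0 + theta) + rho = D.
  theta_star <- (asin((D - rho) / L) - phi0) * 180 / pi
  list(model = model, theta_star = theta_star)
}
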