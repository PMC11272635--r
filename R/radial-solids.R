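#' @title Constructive solid geometry of the parametric hip
#'
#' @description
#' Both bones are defined as star-shaped solids (or a two-sheet radial shell,
#' for the periacetabular pelvis) whose boundary is a single-valued radial
#' function of direction. The femur is the radial hull of a head sphere, a
#' neck capsule, a proximal shaft capsule, and a cam prominence modeled as a
#' spherical-cap thickening spanning the alpha arc. The pelvis is a curved
#' bony plate around the acetabulum: an inner sheet carrying the hemispherical
#' cup (radius = head radius + 1 mm cartilage-free joint clearance) that
#' flares away from the joint beyond the rim, an outer cortical sheet at a
#' fixed plate thickness carrying the AIIS prominence, and a side wall
#' closing the plate.
#'
#' The radial formulation gives three things at once: watertight meshes by
#' construction (a polar grid sampled from the radial function), exact
#' point-membership tests used by the voxel-overlap test oracle, and a direct
#' mapping from each anatomical parameter to one constructive control.
#'
#' All functions here are internal; users interact through [generate_hip()].
#' @name radial_solids
#' @keywords internal
NULL

# ---- shared shape constants (generator design choices, see vignette) --------

gen_constants <- function() {
  list(
    clearance    = 1.0,    # cartilage-free joint space, mm
    cup_delta    = 38,     # cup axis elevation above medial (inclination), deg
    band_min     = 8,      # plate width beyond the rim, away from the AIIS, deg
    band_max     = 22,     # plate width in the AIIS sector, deg
    band_sigma   = 50,     # azimuthal falloff of the plate width, deg
    plate_T0     = 8,      # cortical plate thickness, mm
    flare_amp    = 40,     # inner-sheet flare at the dome edge, mm
    aiis_height  = 8,      # AIIS prominence height above the cortex, mm
    aiis_width   = 22,     # AIIS bump support radius (great-circle), deg
    aiis_beta    = -65,    # AIIS azimuth about the cup axis (anterosuperior,
                           # the subspine sector the flexed cam sweeps), deg
    aiis_drop    = c(I = -6, II = 0, III = 4.5),  # apex height vs rim plane, mm
    neck_len_f   = 2.0,    # neck length as multiple of head radius
    shaft_len    = 60,     # proximal shaft length below neck base, mm
    shaft_rad_f  = 0.58,   # shaft radius as multiple of head radius
    cam_onset    = 42,     # alpha below which the head stays spherical, deg
    cam_slope    = 0.12,   # cam ramp, mm per degree of arc
    cam_hmax     = 4,      # cam prominence height cap, mm
    cam_azimuth  = 40,     # cam apex azimuth in the neck frame, deg
    cam_halfw    = 80,     # cam azimuthal half-width, deg
    sphere_tol   = 0.02,   # sphericity tolerance for the alpha measurement
    knee_dist    = 400,    # head-to-knee distance, mm
    epi_halfw    = 40,     # epicondyle offset from knee center, mm
    asis_x       = 55, asis_z = 95, asis_y_same = -20, asis_y_contra = 190,
    cup_mask_margin = 2,   # deg inside the rim excluded as articular surface
    cup_mask_depth  = 3    # mm above the cup surface treated as articular
  )
}

# ---- femur solid -------------------------------------------------------------

# Build the analytic femur description (canonical right hip, head center at
# the origin, +X anterior +Y left +Z cranial, mechanical axis along -Z).
femur_solid <- function(alpha, femoral_version, head_radius,
                        neck_shaft_angle = 128, k = gen_constants()) {
  R <- head_radius
  psi_ns <- 180 - neck_shaft_angle     # neck axis angle from distal shaft dir
  a0 <- c(0, -sin(deg2rad(psi_ns)), -cos(deg2rad(psi_ns)))
  a  <- as.numeric(rotation_about(c(0, 0, 1), -femoral_version) %*% a0)
  rho <- 1.02 * R * sin(deg2rad(min(alpha, k$cam_onset)))
  L_neck <- k$neck_len_f * R
  P1 <- L_neck * a                           # neck base
  P2 <- P1 + c(0, 0, -k$shaft_len)           # proximal shaft end
  # cam frame: n1 ~ anterior, n2 ~ superior, both orthogonal to the neck axis
  l <- c(0, 0, -1)
  n1 <- unitv(pracma_cross(a, l))
  n2 <- pracma_cross(a, n1)
  if (n2[3] < 0) n2 <- -n2
  has_cam <- alpha > k$cam_onset
  alpha0 <- alpha + k$sphere_tol * R / k$cam_slope  # ramp crosses the
  # sphericity tolerance exactly at the requested alpha arc
  list(R = R, rho = rho, a = a, L_neck = L_neck, P1 = P1, P2 = P2,
       rho_shaft = k$shaft_rad_f * R, n1 = n1, n2 = n2,
       has_cam = has_cam, alpha0 = alpha0,
       cam_slope = k$cam_slope, cam_hmax = k$cam_hmax,
       cam_az = k$cam_azimuth, cam_halfw = k$cam_halfw)
}

# Exit distance of rays from the origin through a capsule (segment q1->q2,
# radius rho). U: n x 3 unit directions. Returns 0 where the ray misses.
.capsule_exit <- function(U, q1, q2, rho) {
  n <- nrow(U)
  best <- numeric(n)
  for (q in list(q1, q2)) {           # end spheres
    b <- U %*% q
    disc <- b^2 - (sum(q * q) - rho^2)
    ok <- disc >= 0
    t <- ifelse(ok, b + sqrt(pmax(disc, 0)), 0)
    best <- pmax(best, t)
  }
  d <- q2 - q1
  L <- sqrt(sum(d^2))
  if (L > 1e-9) {                     # cylinder body
    d <- d / L
    ud <- as.numeric(U %*% d)
    W <- U - outer(ud, d)             # perp component of direction
    c0 <- q1 - sum(q1 * d) * d
    A <- rowSums(W^2)
    B <- as.numeric(W %*% c0)
    C <- sum(c0 * c0) - rho^2
    disc <- B^2 - A * C
    ok <- disc >= 0 & A > 1e-12
    t <- ifelse(ok, (B + sqrt(pmax(disc, 0))) / pmax(A, 1e-12), 0)
    s <- t * ud - sum(q1 * d)         # axial station of the exit point
    t[!(ok & s >= 0 & s <= L)] <- 0
    best <- pmax(best, t)
  }
  best
}

# Radial boundary r(u) of the femur solid. U: n x 3 unit directions
# (femur-local). offset: radial inflation (+) or erosion (-), mm.
femur_radial <- function(U, fs, offset = 0) {
  U <- matrix(U, ncol = 3)
  r <- rep(fs$R, nrow(U))                          # head sphere
  if (fs$has_cam) {
    cpsi <- as.numeric(U %*% fs$a)
    psi <- rad2deg(acos(pmax(-1, pmin(1, cpsi))))
    beta <- rad2deg(atan2(as.numeric(U %*% fs$n2), as.numeric(U %*% fs$n1)))
    dbeta <- abs(((beta - fs$cam_az + 180) %% 360) - 180)
    w <- ifelse(dbeta < fs$cam_halfw, cos(deg2rad(dbeta / fs$cam_halfw * 90))^2, 0)
    h <- pmin(fs$cam_hmax, fs$cam_slope * pmax(fs$alpha0 - psi, 0)) * w
    r <- pmax(r, fs$R + h)
  }
  r <- pmax(r, .capsule_exit(U, c(0, 0, 0), fs$P1, fs$rho))
  r <- pmax(r, .capsule_exit(U, fs$P1, fs$P2, fs$rho_shaft))
  r + offset
}

# Point membership for the femur solid (femur-local coordinates).
femur_inside <- function(P, fs, offset = 0) {
  P <- matrix(P, ncol = 3)
  d <- sqrt(rowSums(P^2))
  ok <- d > 1e-9
  out <- !logical(nrow(P))
  out[!ok] <- TRUE                                   # the center is inside
  if (any(ok)) {
    U <- P[ok, , drop = FALSE] / d[ok]
    out[ok] <- d[ok] <= femur_radial(U, fs, offset)
  }
  out
}

# ---- pelvis solid ------------------------------------------------------------

# Analytic periacetabular pelvis (canonical right hip, acetabular center at
# the origin). lcea/acetabular_version in degrees; aiis_type in {I, II, III}.
pelvis_solid <- function(lcea, acetabular_version, head_radius, aiis_type,
                         k = gen_constants()) {
  R_cup <- head_radius + k$clearance
  # cup axis (pointing into the bone): fixed anatomic inclination, rotated
  # about Z for version; the acetabular coverage half-angle is solved so the
  # lateral center-edge angle measured at the rim (roof-edge protocol, same
  # as measure_lcea on the rim landmarks) hits the request.
  a_cup <- as.numeric(rotation_about(c(0, 0, 1), acetabular_version) %*%
                        c(0, cos(deg2rad(k$cup_delta)), sin(deg2rad(k$cup_delta))))
  m1 <- unitv(c(1, 0, 0) - sum(c(1, 0, 0) * a_cup) * a_cup)
  m2 <- pracma_cross(a_cup, m1)
  # the 24 azimuths here match the rim landmark samples, so the generator's
  # coverage solve and the mesh measurement agree exactly
  rim_dirs <- function(tc, n = 24) {
    b <- deg2rad(seq(0, 360, length.out = n + 1)[-(n + 1)])
    cos(deg2rad(tc)) * matrix(a_cup, n, 3, byrow = TRUE) +
      sin(deg2rad(tc)) * (outer(cos(b), m1) + outer(sin(b), m2))
  }
  lcea_of <- function(tc) {
    Ud <- rim_dirs(tc)
    lat <- -Ud[, 2]; z <- Ud[, 3]
    sel <- which(z > 0)
    if (!length(sel)) return(NA_real_)
    i <- sel[which.max(lat[sel])]          # lateral edge of the roof
    rad2deg(atan2(lat[i], z[i]))
  }
  f <- function(tc) lcea_of(tc) - lcea
  lo <- 48; hi <- 112
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    stop("infeasible parameter combination: no cup coverage attains LCEA = ",
         lcea, " deg at version ", acetabular_version, " deg", call. = FALSE)
  theta_cov <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  theta_dome <- theta_cov + k$band_max     # maximal plate extent (AIIS sector)

  # AIIS apex: fixed anterosuperior azimuth about the cup axis; polar angle
  # solved so the apex height relative to the rim plane encodes the Hetsroni
  # morphotype.
  beta_a <- k$aiis_beta
  rim_offset <- -R_cup * cos(deg2rad(theta_cov))     # rim plane along opening
  band_at <- function(beta) {
    db <- ((beta - beta_a + 180) %% 360) - 180
    k$band_min + (k$band_max - k$band_min) * exp(-(db / k$band_sigma)^2)
  }
  flare <- function(gamma, band) {
    ifelse(gamma > theta_cov,
           k$flare_amp * ((gamma - theta_cov) / band)^2, 0)
  }
  apex_height <- function(gamma) {
    r <- R_cup + flare(gamma, k$band_max) + k$plate_T0 + k$aiis_height
    r * (-cos(deg2rad(gamma))) - rim_offset
  }
  target <- k$aiis_drop[[aiis_type]]
  if (aiis_type == "III") {
    # shallow cups cannot carry the prominence very far below the rim plane;
    # any apex clearly below it still satisfies the morphotype, so the drop
    # is capped at what the plate extent allows
    hmax <- apex_height(theta_dome - 2)
    target <- min(target, hmax - 0.5)
    if (target < 1.5)
      stop("infeasible parameter combination: AIIS apex cannot extend ",
           "below the rim plane for this cup geometry (type III)",
           call. = FALSE)
  }
  g_af <- function(gamma) apex_height(gamma) - target
  if (g_af(50) * g_af(theta_dome - 2) > 0)
    stop("infeasible parameter combination: AIIS apex height target ",
         "unreachable for type ", aiis_type, call. = FALSE)
  gamma_a <- stats::uniroot(g_af, c(50, theta_dome - 2), tol = 1e-6)$root
  u_apex <- cos(deg2rad(gamma_a)) * a_cup +
    sin(deg2rad(gamma_a)) * (cos(deg2rad(beta_a)) * m1 + sin(deg2rad(beta_a)) * m2)

  list(R_cup = R_cup, a_cup = a_cup, m1 = m1, m2 = m2, delta = k$cup_delta,
       theta_cov = theta_cov, theta_dome = theta_dome, band_at = band_at,
       T0 = k$plate_T0, flare_amp = k$flare_amp,
       aiis = list(u_apex = u_apex, gamma_a = gamma_a, beta_a = beta_a,
                   A = k$aiis_height, W = k$aiis_width, type = aiis_type),
       rim_offset = rim_offset, k = k)
}

# Inner/outer sheet radii for unit directions U (pelvis-local). The local
# dome extent is theta_cov + band(beta): widest in the AIIS sector, narrow
# elsewhere (bone recedes quickly away from the subspine region). gamma_max
# gives the local dome edge; directions beyond it carry no bone.
pelvis_sheets <- function(U, ps) {
  U <- matrix(U, ncol = 3)
  cg <- pmax(-1, pmin(1, as.numeric(U %*% ps$a_cup)))
  gamma <- rad2deg(acos(cg))
  beta <- rad2deg(atan2(as.numeric(U %*% ps$m2), as.numeric(U %*% ps$m1)))
  band <- ps$band_at(beta)
  fl <- ifelse(gamma > ps$theta_cov,
               ps$flare_amp * ((gamma - ps$theta_cov) / band)^2, 0)
  r_in <- ps$R_cup + fl
  dist <- rad2deg(acos(pmax(-1, pmin(1, as.numeric(U %*% ps$aiis$u_apex)))))
  w <- ifelse(dist < ps$aiis$W, (1 - (dist / ps$aiis$W)^2)^2, 0)
  r_out <- r_in + ps$T0 + ps$aiis$A * w
  list(gamma = gamma, r_in = r_in, r_out = r_out,
       gamma_max = ps$theta_cov + band)
}

# Point membership for the pelvis shell (pelvis-local coordinates). Negative
# offset erodes the shell, positive inflates it (used by the test oracle's
# ambiguity band).
pelvis_inside <- function(P, ps, offset = 0) {
  P <- matrix(P, ncol = 3)
  d <- sqrt(rowSums(P^2))
  ok <- d > 1e-9
  res <- logical(nrow(P))
  if (any(ok)) {
    U <- P[ok, , drop = FALSE] / d[ok]
    sh <- pelvis_sheets(U, ps)
    ang_off <- rad2deg(offset / pmax(d[ok], 1))      # offset at the dome edge
    res[ok] <- sh$gamma <= sh$gamma_max + ang_off &
      d[ok] >= sh$r_in - offset & d[ok] <= sh$r_out + offset
  }
  res
}

# Articular-surface (joint space) mask: points on/near the cup that are
# excluded from impingement. Used identically by the mesh face labeling and
# by the voxel oracle.
pelvis_cup_region <- function(P, ps) {
  P <- matrix(P, ncol = 3)
  d <- sqrt(rowSums(P^2))
  U <- P / pmax(d, 1e-9)
  gamma <- rad2deg(acos(pmax(-1, pmin(1, as.numeric(U %*% ps$a_cup)))))
  gamma <= ps$theta_cov - ps$k$cup_mask_margin &
    d <= ps$R_cup + ps$k$cup_mask_depth
}
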