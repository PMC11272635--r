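#' Acetabular impingement-region classification
#'
#' Contact sites are classified in the lateral (sagittal) view, as angular
#' sectors around the acetabular center in the projection plane orthogonal
#' to the pelvic lateral axis. Region A (AIIS/subspine) is the wedge bounded
#' by the rays through the two morphological inflection points flanking the
#' AIIS: between the ASIS and the AIIS, and between the AIIS and the
#' anterior acetabular rim. Region B is the rim arc anterior(-inferior) to
#' the wedge, down to the inferior rim extreme; region C is the remaining
#' posterolateral arc. Points on the wedge boundary belong to A.
#'
#' @name region_map
NULL

.circ <- function(x) x %% 360

# sweep from `from` to `to` along direction dir (+1/-1), in [0, 360)
.sweep <- function(from, to, dir) .circ((to - from) * dir)

#' Build the region sectors from pelvis landmarks
#'
#' @param pelvis pelvis [bone_mesh()] with AIIS and inflection landmarks and
#'   rim samples.
#' @param frame the pelvis [define_fpp()] frame (in the same pose as the
#'   mesh).
#' @param side hip side (defaults from mesh hints).
#' @return object of class `region_sectors`.
#' @export
build_sectors <- function(pelvis, frame = define_fpp(pelvis), side = NULL) {
  check_landmarks(pelvis, required_pelvis_landmarks, rim_samples = TRUE)
  if (is.null(side))
    side <- if (identical(pelvis$hints$side, -1)) "left" else "right"
  ctr <- pelvis$landmarks$acetabular_center
  ant <- frame$axes[, 1]; cran <- frame$axes[, 3]
  proj_angle <- function(p) {
    rel <- p - ctr
    u <- sum(rel * ant); w <- sum(rel * cran)
    if (sqrt(u^2 + w^2) < 1e-9)
      stop("point projects onto the acetabular center", call. = FALSE)
    rad2deg(atan2(w, u))
  }
  phi1 <- proj_angle(pelvis$landmarks$inflection_ASIS_AIIS)
  phi2 <- proj_angle(pelvis$landmarks$inflection_AIIS_rim)
  phia <- proj_angle(pelvis$landmarks$AIIS_apex)
  dir <- 1
  if (!(.sweep(phi1, phia, 1) <= .sweep(phi1, phi2, 1))) dir <- -1
  width <- .sweep(phi1, phi2, dir)
  if (.sweep(phi1, phia, dir) > width || width > 180)
    stop("landmark inconsistency: AIIS apex outside the inflection wedge",
         call. = FALSE)
  rs <- rim_samples(pelvis)
  w_rim <- as.numeric(sweep(rs, 2, ctr) %*% cran)
  cut_pt <- rs[which.min(w_rim), ]             # inferior rim extreme
  phic <- proj_angle(cut_pt)
  structure(list(center = ctr, anterior = ant, cranial = cran,
                 phi_asis = phi1, phi_rim = phi2, phi_cut = phic,
                 dir = dir, side = side),
            class = "region_sectors")
}

#' @export
print.region_sectors <- function(x, ...) {
  cat(sprintf(paste0("region_sectors (%s hip): wedge A [%.1f, %.1f] deg, ",
                     "B/C cut at %.1f deg (sagittal projection)\n"),
              x$side, x$phi_asis, x$phi_rim, x$phi_cut))
  invisible(x)
}

#' Classify a contact point into region A, B or C
#'
#' @param point 3D contact point (on or near the pelvis surface).
#' @param sectors a [build_sectors()] object.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
classify_contact <- function(point, sectors) {
  rel <- point - sectors$center
  u <- sum(rel * sectors$anterior); w <- sum(rel * sectors$cranial)
  if (sqrt(u^2 + w^2) < 1e-9)
    stop("point projects onto the acetabular center", call. = FALSE)
  phi <- rad2deg(atan2(w, u))
  tol <- rad2deg(1e-6)
  dir <- sectors$dir
  wA <- .sweep(sectors$phi_asis, sectors$phi_rim, dir)
  sA <- .sweep(sectors$phi_asis, phi, dir)
  if (sA <= wA + tol || sA >= 360 - tol) return("A")
  sB <- .sweep(sectors$phi_rim, phi, dir)
  wB <- .sweep(sectors$phi_rim, sectors$phi_cut, dir)
  if (sB <= wB) return("B")
  "C"
}
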