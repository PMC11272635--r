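#' Read and write surface meshes and landmark files
#'
#' Meshes are exchanged as binary STL (de-duplicating vertices on read) or
#' PLY (ascii). Landmarks travel in a JSON side-car file mapping landmark
#' name to an `[x, y, z]` position in mm, in the same right-handed coordinate
#' system as the mesh (+X anterior, +Y left, +Z cranial).
#'
#' @param mesh a `bone_mesh`.
#' @param path output file path.
#' @return `write_*` return `path` invisibly; `read_*` return a `bone_mesh`
#'   (landmark-free unless a JSON file is supplied to [read_landmarks_json()]).
#' @name mesh_io
NULL

#' @rdname mesh_io
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "hipimpinge binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  rec <- t(cbind(n, a, b, cc))  # 12 floats per facet, column-per-face
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(rec[, i]), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  dat <- readBin(con, "raw", nf * 50)
  stopifnot(length(dat) == nf * 50)
  m <- matrix(dat, nrow = 50)
  floats <- matrix(readBin(as.raw(m[1:48, ]), "numeric", size = 4,
                           n = 12 * nf, endian = "little"), nrow = 12)
  tri <- array(floats[4:12, ], dim = c(3, 3, nf))  # xyz x corner x face
  pts <- matrix(aperm(tri, c(2, 3, 1)), ncol = 3)  # corners stacked
  key <- paste(signif(pts[, 1], 10), signif(pts[, 2], 10), signif(pts[, 3], 10))
  idx <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  bone_mesh(verts, faces, check = FALSE)
}

#' @rdname mesh_io
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  vl <- lines[(hdr_end + 1):(hdr_end + nv)]
  fl <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  v <- matrix(as.numeric(unlist(strsplit(vl, " +"))), ncol = 3, byrow = TRUE)
  fparts <- matrix(as.integer(unlist(strsplit(fl, " +"))), ncol = 4, byrow = TRUE)
  stopifnot(all(fparts[, 1] == 3L))
  bone_mesh(v, fparts[, 2:4] + 1L, check = FALSE)
}

#' @rdname mesh_io
#' @export
write_landmarks_json <- function(mesh, path) {
  jsonlite::write_json(lapply(mesh$landmarks, as.numeric), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a landmark JSON file into a named list
#' @param path JSON file of `{"name": [x,y,z], ...}`.
#' @return named list of numeric length-3 points.
#' @export
read_landmarks_json <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.numeric)
}
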