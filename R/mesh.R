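# Closed triangulated organ surfaces: the patient-specific geometry every
# downstream stage (voxelization, FE simulation, visibility) is built on.

#' Construct a closed triangulated surface mesh
#'
#' Validates the watertightness and orientation invariants required by the
#' voxelizer and the signed distance field: every edge shared by exactly two
#' faces, consistent winding (each directed edge used once), and positive
#' enclosed volume (outward orientation). Positions are in meters.
#'
#' @param vertices numeric matrix (n x 3) of vertex positions in meters.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param validate logical; check the invariants (default TRUE).
#' @return an object of class \code{surface_mesh} with fields
#'   \code{vertices}, \code{faces}, \code{normals} (per-vertex outward unit
#'   normals).
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  if (validate) {
    if (!is_watertight(vertices, faces))
      stop("mesh is not watertight / consistently oriented")
    if (enclosed_volume(vertices, faces) <= 0)
      stop("mesh has non-positive enclosed volume (inward orientation?)")
  }
  m <- list(vertices = vertices, faces = faces,
            normals = vertex_normals(vertices, faces))
  class(m) <- "surface_mesh"
  m
}

is_watertight <- function(vertices, faces) {
  # directed half-edges: consistent orientation <=> each appears exactly once
  # and its opposite exactly once
  he <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key)) return(FALSE)
  opp <- paste(he[, 2], he[, 1])
  all(opp %in% key)
}

enclosed_volume <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
          a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
          a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det3) / 6
}

#' Enclosed volume of a surface mesh (divergence theorem)
#' @param mesh a \code{surface_mesh}.
#' @return volume in cubic meters.
#' @export
mesh_volume <- function(mesh) enclosed_volume(mesh$vertices, mesh$faces)

vertex_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted
  vn <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], group = faces[, k])
      ids <- as.integer(rownames(acc))
      vn[ids, d] <- vn[ids, d] + acc
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

#' Bounding-box extents of a mesh
#' @param mesh a \code{surface_mesh}.
#' @return list with \code{lo}, \code{hi}, \code{extent} (meters).
#' @export
mesh_bounds <- function(mesh) {
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  list(lo = lo, hi = hi, extent = hi - lo)
}

#' @export
print.surface_mesh <- function(x, ...) {
  b <- mesh_bounds(x)
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  extent [m]: %.4f x %.4f x %.4f, volume %.3e m^3\n",
              b$extent[1], b$extent[2], b$extent[3], mesh_volume(x)))
  invisible(x)
}
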