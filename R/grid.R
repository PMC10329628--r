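# Regular grids with cubic cells: the shared coordinate system of the FE
# mesh, the distance-field inputs and the attachment mask.  Cells are
# addressed 0-based in (i, j, k) with x fastest; all positions in meters.

#' Construct a regular grid
#'
#' @param origin grid corner position (m), the minimum corner of cell (0,0,0).
#' @param spacing cubic cell edge length (m), one value for all axes.
#' @param dims integer cell counts (n_x, n_y, n_z).
#' @return an object of class \code{regular_grid}.
#' @export
regular_grid <- function(origin, spacing, dims) {
  stopifnot(length(origin) == 3, length(dims) == 3, spacing > 0, all(dims >= 2))
  g <- list(origin = as.numeric(origin), spacing = as.numeric(spacing),
            dims = as.integer(dims))
  class(g) <- "regular_grid"
  g
}

#' Fit a regular grid around a surface mesh
#'
#' Chooses a single cubic spacing (the maximum over axes of
#' extent / (dims - 2)) so that the grid's bounding box covers the mesh with
#' at least a one-cell margin on every axis; the grid is centered on the
#' mesh. Because the spacing is shared, the grid may overhang the organ on
#' its short axes.
#'
#' @param mesh a \code{surface_mesh}.
#' @param target_dims integer cell counts per axis, each >= 3; the default
#'   31 x 32 x 26 suits a patient liver at centimeter resolution.
#' @return a \code{regular_grid}.
#' @export
fit_grid <- function(mesh, target_dims = c(31L, 32L, 26L)) {
  stopifnot(inherits(mesh, "surface_mesh"))
  dims <- as.integer(target_dims)
  if (any(dims < 3L)) stop("target_dims must be >= 3 per axis (one-cell margin)")
  b <- mesh_bounds(mesh)
  if (any(b$extent <= 0)) stop("degenerate mesh: zero extent on some axis")
  # divisor dims - 2.5 leaves at least 1.25 cells of margin per side, so
  # exact-touch roundoff can never place a kept cell on the grid boundary
  spacing <- max(b$extent / (dims - 2.5))
  center <- (b$lo + b$hi) / 2
  origin <- center - dims * spacing / 2
  regular_grid(origin, spacing, dims)
}

#' Voxel-center coordinates of a grid
#' @param grid a \code{regular_grid}.
#' @return matrix (prod(dims) x 3), rows in x-fastest cell order.
#' @export
grid_centers <- function(grid) {
  d <- grid$dims
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1)))
  sweep((ijk + 0.5) * grid$spacing, 2, grid$origin, `+`)
}

# 0-based (i,j,k) -> 1-based linear index, x fastest
cell_index <- function(ijk, dims) {
  ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3]) + 1L
}

#' @export
print.regular_grid <- function(x, ...) {
  cat(sprintf("regular_grid: %d x %d x %d cells, spacing %.4f m\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}

#' Signed distance field of a watertight mesh on a grid
#'
#' At each voxel center the unsigned Euclidean distance to the mesh surface,
#' negated inside the mesh (inside/outside decided by generalized winding
#' number).
#'
#' @param mesh a watertight \code{surface_mesh}.
#' @param grid a \code{regular_grid}.
#' @return numeric 3D array of dim \code{grid$dims} (meters).
#' @export
signed_distance_field <- function(mesh, grid) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(grid, "regular_grid"))
  if (!is_watertight(mesh$vertices, mesh$faces))
    stop("signed distance undefined for a non-watertight mesh")
  centers <- grid_centers(grid)
  f0 <- mesh$faces - 1L
  d <- cpp_dist_to_mesh(centers, mesh$vertices, f0)
  w <- cpp_winding_number(centers, mesh$vertices, f0)
  array(ifelse(w > 0.5, -d, d), dim = grid$dims)
}
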