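# Embedding a closed surface into a regular grid: cells inside the organ or
# overlapping its boundary are kept and assembled into a hexahedral FE mesh
# with a one-to-one node <-> voxel correspondence (each node carries the
# grid coordinate of the cell whose minimum corner it is), which is what
# makes the network's voxel mask directly transferable to FE constraints.

# local corner offsets, VTK hexahedron ordering
HEX_CORNERS <- rbind(c(0L,0L,0L), c(1L,0L,0L), c(1L,1L,0L), c(0L,1L,0L),
                     c(0L,0L,1L), c(1L,0L,1L), c(1L,1L,1L), c(0L,1L,1L))

# boundary faces: local corner ids (rows) per axis direction
HEX_FACES <- list(
  xm = list(local = c(1L,5L,8L,4L), dir = c(-1,0,0), nb = c(-1L,0L,0L)),
  xp = list(local = c(2L,3L,7L,6L), dir = c(1,0,0),  nb = c(1L,0L,0L)),
  ym = list(local = c(1L,2L,6L,5L), dir = c(0,-1,0), nb = c(0L,-1L,0L)),
  yp = list(local = c(4L,8L,7L,3L), dir = c(0,1,0),  nb = c(0L,1L,0L)),
  zm = list(local = c(1L,4L,3L,2L), dir = c(0,0,-1), nb = c(0L,0L,-1L)),
  zp = list(local = c(5L,6L,7L,8L), dir = c(0,0,1),  nb = c(0L,0L,1L))
)

#' Voxelize a surface mesh into a hexahedral FE model
#'
#' Keeps the grid cells whose center lies inside the mesh (generalized
#' winding number > 1/2) or that intersect a mesh triangle (separating-axis
#' test), deduplicates the shared cell corners into FE nodes, and extracts
#' the boundary of the kept region.
#'
#' @param mesh a watertight \code{surface_mesh}.
#' @param grid a \code{regular_grid} containing the mesh with a one-cell
#'   margin (see \code{\link{fit_grid}}).
#' @return an object of class \code{hex_model} with fields \code{nodes}
#'   (n x 3 positions), \code{hexes} (m x 8, 1-based, VTK ordering),
#'   \code{kept_cells} (1-based linear cell indices, x fastest),
#'   \code{surface_nodes}, \code{surface_faces} (boundary quads),
#'   \code{surface_normals} (outward unit normals at surface nodes),
#'   \code{node_to_voxel} (n x 3, 0-based grid coordinate per node) and
#'   \code{grid}.
#' @export
voxelize <- function(mesh, grid) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(grid, "regular_grid"))
  d <- grid$dims
  centers <- grid_centers(grid)
  f0 <- mesh$faces - 1L
  inside <- cpp_winding_number(centers, mesh$vertices, f0) > 0.5
  overlap <- cpp_cells_intersecting(mesh$vertices, f0, grid$origin,
                                    grid$spacing, d) > 0L
  kept <- which(inside | overlap)
  if (length(kept) == 0L) stop("mesh outside grid: no cell kept")
  kk <- kept - 1L
  ijk <- cbind(kk %% d[1], (kk %/% d[1]) %% d[2], kk %/% (d[1] * d[2]))
  if (any(ijk == 0L) || any(sweep(ijk, 2, d - 1L, `==`)))
    stop("kept cells touch the grid boundary; enlarge the grid (one-cell margin required)")

  nd <- d + 1L
  corner_lin <- function(cijk) cijk[, 1] + nd[1] * (cijk[, 2] + nd[2] * cijk[, 3])
  m <- length(kept)
  hex_corner_lin <- matrix(0L, m, 8L)
  for (a in 1:8)
    hex_corner_lin[, a] <- corner_lin(sweep(ijk, 2, HEX_CORNERS[a, ], `+`))
  ulin <- sort(unique(as.vector(hex_corner_lin)))
  hexes <- matrix(match(hex_corner_lin, ulin), m, 8L)
  cijk <- cbind(ulin %% nd[1], (ulin %/% nd[1]) %% nd[2], ulin %/% (nd[1] * nd[2]))
  nodes <- sweep(cijk * grid$spacing, 2, grid$origin, `+`)

  kept_set <- logical(prod(d))
  kept_set[kept] <- TRUE
  faces <- vector("list", 6L * m)
  dirs <- vector("list", 6L * m)
  q <- 0L
  for (fc in HEX_FACES) {
    nb <- sweep(ijk, 2, fc$nb, `+`)
    nb_idx <- cell_index(nb, d)
    exposed <- which(!kept_set[nb_idx])
    for (e in exposed) {
      q <- q + 1L
      faces[[q]] <- hexes[e, fc$local]
      dirs[[q]] <- fc$dir
    }
  }
  surface_faces <- do.call(rbind, faces[seq_len(q)])
  surface_face_dirs <- do.call(rbind, dirs[seq_len(q)])
  surface_nodes <- sort(unique(as.vector(surface_faces)))
  normals <- matrix(0, nrow(nodes), 3)
  for (r in seq_len(q))
    normals[surface_faces[r, ], ] <- sweep(normals[surface_faces[r, ], , drop = FALSE],
                                           2, surface_face_dirs[r, ], `+`)
  len <- sqrt(rowSums(normals^2)); len[len == 0] <- 1
  normals <- normals / len

  model <- list(cache = new.env(parent = emptyenv()),
                nodes = nodes, hexes = hexes, kept_cells = kept,
                surface_nodes = surface_nodes, surface_faces = surface_faces,
                surface_face_dirs = surface_face_dirs,
                surface_normals = normals, node_to_voxel = cijk, grid = grid)
  class(model) <- "hex_model"
  model
}

#' @export
print.hex_model <- function(x, ...) {
  cat(sprintf("hex_model: %d nodes, %d hex cells (%d surface nodes)\n",
              nrow(x$nodes), nrow(x$hexes), length(x$surface_nodes)))
  cat(sprintf("  grid %d x %d x %d, spacing %.4f m\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3], x$grid$spacing))
  invisible(x)
}

# characteristic model size: bounding-box diagonal of the rest nodes
model_diameter <- function(model) {
  sqrt(sum((apply(model$nodes, 2, max) - apply(model$nodes, 2, min))^2))
}
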