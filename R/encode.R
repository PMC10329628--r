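# Grid encodings: the network's input distance fields (one per deformed
# view) and the binary attachment mask output, plus the displacement-based
# legacy encoding used by the original single-view architecture for the
# input-representation comparison.

#' Encode one sample as distance fields and an attachment mask
#'
#' Each frame's visible deformed surface becomes a distance field: at every
#' voxel center the Euclidean distance to the nearest visible point, divided
#' by the grid bounding-box diagonal (so values live in [0, 1]), and clamped
#' to exactly 0 in voxels that contain a visible point. The attachment is a
#' binary mask with 1 at the voxel of each attachment node under the model's
#' node-to-voxel correspondence.
#'
#' @param sample a sample record (list with \code{attachment} and
#'   \code{frames}, as built by \code{\link{generate_dataset}}).
#' @param model the \code{hex_model} the sample was simulated on.
#' @return list with \code{df} (array F x nx x ny x nz) and \code{mask}
#'   (array nx x ny x nz of 0/1).
#' @export
encode_sample <- function(sample, model) {
  grid <- model$grid
  FF <- length(sample$frames)
  d <- grid$dims
  df <- array(0, dim = c(FF, d))
  for (f in seq_len(FF)) {
    fr <- sample$frames[[f]]
    pts <- model$nodes[fr$visible_nodes, , drop = FALSE] +
      fr$displacements[fr$visible_nodes, , drop = FALSE]
    df[f, , , ] <- encode_distance_field(pts, grid)
  }
  list(df = df, mask = encode_mask(sample$attachment$nodes, model))
}

#' Distance field of a point cloud on a grid
#'
#' @param points (n x 3) positions in meters (e.g. a deformed visible
#'   surface cloud).
#' @param grid a \code{regular_grid}.
#' @return 3D array of dim \code{grid$dims}, normalized by the grid diagonal.
#' @export
encode_distance_field <- function(points, grid) {
  if (nrow(points) == 0L) stop("visible point set is empty")
  d <- grid$dims
  centers <- grid_centers(grid)
  diag_len <- sqrt(sum((d * grid$spacing)^2))
  val <- cpp_min_point_dist(centers, points) / diag_len
  # voxels containing a point are exactly zero
  ijk <- floor(sweep(points, 2, grid$origin, `-`) / grid$spacing)
  keep <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 & ijk[, 2] < d[2] &
    ijk[, 3] >= 0 & ijk[, 3] < d[3]
  if (any(keep)) val[cell_index(ijk[keep, , drop = FALSE], d)] <- 0
  array(val, dim = d)
}

#' Binary attachment mask of a node set
#' @param nodes attachment node indices.
#' @param model a \code{hex_model}.
#' @return 3D array of dim \code{grid$dims} with entries in \{0, 1\}.
#' @export
encode_mask <- function(nodes, model) {
  d <- model$grid$dims
  mask <- array(0, dim = d)
  if (length(nodes))
    mask[cell_index(model$node_to_voxel[nodes, , drop = FALSE], d)] <- 1
  mask
}

#' Decode an attachment mask back to model nodes
#'
#' Inverse of \code{\link{encode_mask}} under the injective node-to-voxel
#' correspondence.
#'
#' @param mask binary 3D array on the model grid.
#' @param model a \code{hex_model}.
#' @return sorted node indices whose voxel is set in the mask.
#' @export
decode_mask <- function(mask, model) {
  d <- model$grid$dims
  idx <- cell_index(model$node_to_voxel, d)
  which(mask[idx] > 0.5)
}

#' Legacy displacement-based input encoding
#'
#' The original single-view input representation: the per-node displacement
#' of the visible surface splatted onto a grid with a Gaussian kernel
#' (sigma = one cell, kernel weights normalized per node so a unit
#' displacement deposits unit integral), plus a signed-distance-field
#' channel of the rest geometry.
#'
#' @param sample a sample record (frame 1 is used).
#' @param model the \code{hex_model}.
#' @param mesh the rest \code{surface_mesh} (for the SDF channel).
#' @param grid the legacy encoding grid (historically 64^3; any
#'   \code{regular_grid} covering the organ works).
#' @param frame which frame to encode (default 1).
#' @param sdf optional precomputed signed distance field of \code{mesh} on
#'   \code{grid} (it is the same for every sample; passing it avoids
#'   recomputation across a dataset).
#' @return array 4 x nx x ny x nz: 3 displacement channels + 1 SDF channel.
#' @export
encode_legacy <- function(sample, model, mesh, grid, frame = 1L, sdf = NULL) {
  fr <- sample$frames[[frame]]
  vis <- fr$visible_nodes
  pos <- model$nodes[vis, , drop = FALSE]
  disp <- fr$displacements[vis, , drop = FALSE]
  d <- grid$dims
  out <- array(0, dim = c(4, d))
  splat <- gaussian_splat(pos, disp, grid)
  for (ch in 1:3) out[ch, , , ] <- splat[, , , ch]
  out[4, , , ] <- if (is.null(sdf)) signed_distance_field(mesh, grid) else sdf
  out
}

# Gaussian splat of per-point vectors onto the grid; sigma = 1 cell, support
# truncated at 3 sigma, weights normalized per point.
gaussian_splat <- function(pos, vec, grid) {
  d <- grid$dims
  acc <- array(0, dim = c(d, ncol(vec)))
  rad <- 3L
  offs <- as.matrix(expand.grid(-rad:rad, -rad:rad, -rad:rad))
  offs <- offs[rowSums(offs^2) <= (rad + 0.5)^2, , drop = FALSE]
  base <- floor(sweep(pos, 2, grid$origin, `-`) / grid$spacing)
  for (p in seq_len(nrow(pos))) {
    ijk <- sweep(offs, 2, as.integer(base[p, ]), `+`)
    ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 & ijk[, 2] < d[2] &
      ijk[, 3] >= 0 & ijk[, 3] < d[3]
    ijk <- ijk[ok, , drop = FALSE]
    if (!nrow(ijk)) next
    centers <- sweep((ijk + 0.5) * grid$spacing, 2, grid$origin, `+`)
    r2 <- rowSums(sweep(centers, 2, pos[p, ], `-`)^2)
    w <- exp(-r2 / (2 * grid$spacing^2))
    w <- w / sum(w)
    lin <- cell_index(ijk, d)
    for (ch in seq_len(ncol(vec))) {
      slice <- (ch - 1L) * prod(d)
      acc[slice + lin] <- acc[slice + lin] + w * vec[p, ch]
    }
  }
  acc
}
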