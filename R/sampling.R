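# Randomized constraint sampling on the hex-model surface: attachment
# regions (the quantity to be learned), force patches (the manipulation) and
# partial visible surfaces (the observation).  Regions are grown from a seed
# node by a score combining Euclidean distance and uniform noise, giving
# irregular but connected-ish patches.

# k surface nodes with the lowest distance+noise score around seed_node
grow_region <- function(model, candidates, seed_node, k, eta) {
  pos <- model$nodes[candidates, , drop = FALSE]
  d <- sqrt(rowSums(sweep(pos, 2, model$nodes[seed_node, ], `-`)^2))
  score <- d + eta * stats::runif(length(candidates))
  candidates[order(score)[seq_len(min(k, length(candidates)))]]
}

#' Sample a random attachment region on the model surface
#'
#' Draws a coverage fraction uniformly from \code{coverage_range}, picks a
#' random surface seed node, and grows the region by the lowest values of
#' score_i = |x_i - x_seed| + eta * U(0,1), eta = \code{noise_frac} times
#' the model diameter. The realized coverage is clamped to the range.
#'
#' @param model a \code{hex_model}.
#' @param coverage_range fraction of surface nodes covered, default
#'   c(0.05, 0.50).
#' @param noise_frac noise scale as a fraction of the model diameter
#'   (default 0.3); 0 gives the exact k-nearest-neighbour region.
#' @return list with \code{nodes}, \code{coverage}, \code{seed_node}.
#' @export
sample_attachment <- function(model, coverage_range = c(0.05, 0.50),
                              noise_frac = 0.3) {
  sn <- model$surface_nodes
  stopifnot(length(sn) > 0)
  ns <- length(sn)
  coverage <- stats::runif(1, coverage_range[1], coverage_range[2])
  k <- round(coverage * ns)
  k <- max(k, ceiling(coverage_range[1] * ns), 1L)
  k <- min(k, floor(coverage_range[2] * ns))
  seed_node <- sn[sample.int(ns, 1)]
  eta <- noise_frac * model_diameter(model)
  nodes <- grow_region(model, sn, seed_node, k, eta)
  list(nodes = sort(nodes), coverage = k / ns, seed_node = seed_node)
}

#' Sample a random force patch disjoint from the attachment
#'
#' A small surface patch (1-5 percent of surface nodes by default) grown
#' among the non-attached surface nodes, loaded with a total force of random
#' magnitude split uniformly over the patch, in a direction uniform on the
#' sphere.
#'
#' @param model a \code{hex_model}.
#' @param attachment attachment region (list as returned by
#'   \code{\link{sample_attachment}}) whose nodes the patch must avoid.
#' @param patch_range patch coverage range as fraction of surface nodes.
#' @param magnitude_range total force magnitude range in Newton, default
#'   c(0.1, 20): calibrated so realized deformations span millimeters to
#'   near the 0.3 m stability cap and the rejection filter is operative.
#' @param noise_frac region-growth noise scale (fraction of model diameter).
#' @return list with \code{patch_nodes}, \code{direction} (unit),
#'   \code{magnitude} (N, total over the patch).
#' @export
sample_force <- function(model, attachment, patch_range = c(0.01, 0.05),
                         magnitude_range = c(0.1, 20), noise_frac = 0.3) {
  sn <- model$surface_nodes
  free <- setdiff(sn, attachment$nodes)
  if (length(free) == 0L) stop("attachment covers the entire surface")
  k <- max(1L, round(stats::runif(1, patch_range[1], patch_range[2]) * length(sn)))
  seed_node <- free[sample.int(length(free), 1)]
  eta <- noise_frac * model_diameter(model)
  patch <- grow_region(model, free, seed_node, k, eta)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  list(patch_nodes = sort(patch), direction = dir,
       magnitude = stats::runif(1, magnitude_range[1], magnitude_range[2]))
}

force_bcs <- function(attachment, force) {
  npatch <- length(force$patch_nodes)
  boundary_conditions(
    fixed_nodes = attachment$nodes,
    load_nodes = force$patch_nodes,
    load_forces = matrix(rep(force$direction * force$magnitude / npatch,
                             each = npatch), ncol = 3))
}

# nodewise outward normals of the deformed boundary (quad cross products,
# oriented by the rest outward axis of each exposed face)
deformed_surface_normals <- function(model, deformed) {
  nrm <- matrix(0, nrow(model$nodes), 3)
  sf <- model$surface_faces
  p1 <- deformed[sf[, 1], , drop = FALSE]; p2 <- deformed[sf[, 2], , drop = FALSE]
  p3 <- deformed[sf[, 3], , drop = FALSE]; p4 <- deformed[sf[, 4], , drop = FALSE]
  d1 <- p3 - p1; d2 <- p4 - p2
  fn <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  flip <- rowSums(fn * model$surface_face_dirs) < 0
  fn[flip, ] <- -fn[flip, ]
  for (r in seq_len(nrow(sf)))
    nrm[sf[r, ], ] <- sweep(nrm[sf[r, ], , drop = FALSE], 2, fn[r, ], `+`)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm / len
}

#' Extract a partial visible surface under a fixed virtual camera
#'
#' Candidate nodes are deformed surface nodes on camera-facing boundary
#' faces (outward normal . view_dir < 0) that are not occluded by the organ
#' itself; occlusion is decided by marching sample points along the ray
#' toward the camera and testing them against the deformed boundary surface
#' (generalized winding number), which is robust at silhouette steps of the
#' blocky hex boundary. A target coverage fraction of all surface nodes is
#' drawn uniformly from \code{coverage_range} and the visible region is
#' grown within the candidates by the distance+noise score; if the target
#' exceeds the candidate count the whole candidate set is returned.
#'
#' @param model a \code{hex_model}.
#' @param displacements (n_nodes x 3) displacement field of the deformed
#'   state (meters).
#' @param view_dir unit viewing direction (camera to scene); default
#'   c(0, 0, -1), a camera above the organ looking down.
#' @param coverage_range fraction of all surface nodes, default c(0.10, 1.0).
#' @param noise_frac region-growth noise scale (fraction of model diameter).
#' @return list with \code{nodes} (visible surface node indices) and
#'   \code{coverage} (fraction of all surface nodes).
#' @export
extract_visible_surface <- function(model, displacements,
                                    view_dir = c(0, 0, -1),
                                    coverage_range = c(0.10, 1.00),
                                    noise_frac = 0.3) {
  stopifnot(abs(sqrt(sum(view_dir^2)) - 1) < 1e-8)
  sn <- model$surface_nodes
  deformed <- model$nodes + displacements
  nrm <- deformed_surface_normals(model, deformed)
  facing <- sn[(nrm[sn, , drop = FALSE] %*% view_dir) < 0]
  vis <- facing[!occluded_nodes(model, deformed, facing, view_dir)]
  if (length(vis) == 0L) vis <- facing  # cannot happen for watertight meshes
  coverage <- stats::runif(1, coverage_range[1], coverage_range[2])
  k <- max(1L, round(coverage * length(sn)))
  if (k >= length(vis)) {
    nodes <- vis
  } else {
    seed_node <- vis[sample.int(length(vis), 1)]
    eta <- noise_frac * model_diameter(model)
    nodes <- grow_region(model, vis, seed_node, k, eta)
  }
  list(nodes = sort(nodes), coverage = length(nodes) / length(sn))
}

# TRUE for candidate nodes whose ray toward the camera hits the deformed
# boundary surface (triangulated quads).  Rays start a little off the
# surface and triangles are shrunk by a barycentric tolerance so adjacent
# faces and grazing silhouette edges do not register as occluders.
occluded_nodes <- function(model, deformed, candidates, view_dir) {
  if (length(candidates) == 0L) return(logical(0))
  sf <- model$surface_faces
  tris <- rbind(sf[, c(1, 2, 3)], sf[, c(1, 3, 4)]) - 1L
  eps <- 0.35 * model$grid$spacing
  cpp_ray_hits_mesh(deformed[candidates, , drop = FALSE], -view_dir,
                    deformed, tris, tmin = eps, btol = 1e-6) > 0L
}
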