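# Surface meshes, grid fitting, voxelization and the signed distance field.

test_that("fit_grid covers the mesh with a one-cell margin and cubic cells", {
  cube <- unit_cube_mesh()
  g <- fit_grid(cube, c(4, 4, 4))
  expect_true(g$spacing * 4 >= 1 + 2 * g$spacing - 1e-12)
  expect_equal(length(g$spacing), 1L)  # single shared spacing

  # default dims accepted verbatim
  gd <- fit_grid(fixture_mesh())
  expect_identical(gd$dims, c(31L, 32L, 26L))

  # elongated box: one shared spacing, all axes covered (brute-force
  # point-in-box check on every vertex)
  box <- unit_cube_mesh()
  box$vertices <- sweep(box$vertices, 2, c(0.2, 0.1, 0.05), `*`)
  box <- surface_mesh(box$vertices, box$faces)
  gb <- fit_grid(box, c(8, 4, 3))
  lo <- gb$origin + gb$spacing        # one-cell margin inside
  hi <- gb$origin + (gb$dims - 1) * gb$spacing
  inside <- sweep(box$vertices, 2, lo, `>=`) & sweep(box$vertices, 2, hi, `<=`)
  expect_true(all(inside))
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_grid(unit_cube_mesh(), c(2, 4, 4)), "margin")
  # inward-oriented (negative volume) mesh refused
  cube <- unit_cube_mesh()
  expect_error(surface_mesh(cube$vertices, cube$faces[, c(1, 3, 2)]),
               "volume|watertight")
  # mesh entirely outside the grid keeps no cell
  far <- regular_grid(origin = c(10, 10, 10), spacing = 0.5, dims = c(4, 4, 4))
  expect_error(voxelize(cube, far), "outside")
})

# independent separating-axis triangle/box test written in R
tri_box_overlap_r <- function(lo, hi, a, b, c) {
  ctr <- (lo + hi) / 2; h <- (hi - lo) / 2
  v <- rbind(a, b, c) - rep(ctr, each = 3)
  e <- rbind(v[2, ] - v[1, ], v[3, ] - v[2, ], v[1, ] - v[3, ])
  nrm <- c(e[1, 2] * e[2, 3] - e[1, 3] * e[2, 2],
           e[1, 3] * e[2, 1] - e[1, 1] * e[2, 3],
           e[1, 1] * e[2, 2] - e[1, 2] * e[2, 1])
  axes <- rbind(diag(3), nrm)
  for (i in 1:3) for (j in 1:3) {
    ax <- c(e[i, 2] * diag(3)[j, 3] - e[i, 3] * diag(3)[j, 2],
            e[i, 3] * diag(3)[j, 1] - e[i, 1] * diag(3)[j, 3],
            e[i, 1] * diag(3)[j, 2] - e[i, 2] * diag(3)[j, 1])
    axes <- rbind(axes, ax)
  }
  for (r in seq_len(nrow(axes))) {
    ax <- axes[r, ]
    if (sum(ax^2) < 1e-20) next
    proj <- v %*% ax
    rad <- sum(h * abs(ax))
    if (min(proj) > rad || max(proj) < -rad) return(FALSE)
  }
  TRUE
}

test_that("voxelization matches a brute-force inside/intersection oracle", {
  mesh <- sphere_mesh(radius = 0.5, subdivisions = 1)  # 80 faces
  grid <- regular_grid(origin = c(-1, -1, -1), spacing = 1 / 3,
                       dims = c(6, 6, 6))
  model <- voxelize(mesh, grid)

  kept_oracle <- logical(prod(grid$dims))
  idx <- 0
  for (k in 0:5) for (j in 0:5) for (i in 0:5) {
    idx <- idx + 1
    lo <- grid$origin + c(i, j, k) * grid$spacing
    hi <- lo + grid$spacing
    center <- lo + grid$spacing / 2
    inside <- inside_ray_parity(center, mesh$vertices, mesh$faces)
    hit <- FALSE
    for (f in seq_len(nrow(mesh$faces))) {
      if (tri_box_overlap_r(lo, hi, mesh$vertices[mesh$faces[f, 1], ],
                            mesh$vertices[mesh$faces[f, 2], ],
                            mesh$vertices[mesh$faces[f, 3], ])) {
        hit <- TRUE
        break
      }
    }
    kept_oracle[idx] <- inside || hit
  }
  kept <- logical(prod(grid$dims))
  kept[model$kept_cells] <- TRUE
  expect_identical(kept, kept_oracle)
  expect_equal(length(model$kept_cells), sum(kept_oracle))
})

test_that("voxelize deduplicates nodes and exposes the kept-region boundary", {
  m1 <- single_hex_model()
  expect_equal(nrow(m1$hexes), 1L)
  expect_equal(nrow(m1$nodes), 8L)
  expect_equal(sort(m1$surface_nodes), 1:8)

  # two adjacent kept cells: 12 nodes, interior face not on the boundary
  s <- 0.02
  grid <- regular_grid(origin = c(-s, -s, -s), spacing = s, dims = c(4, 3, 3))
  mesh <- sphere_mesh(radius = 0.45 * s, center = c(s / 2, s / 2, s / 2))
  mesh2 <- sphere_mesh(radius = 0.45 * s, center = c(1.5 * s, s / 2, s / 2))
  both <- surface_mesh(rbind(mesh$vertices, mesh2$vertices),
                       rbind(mesh$faces, mesh2$faces + nrow(mesh$vertices)),
                       validate = FALSE)
  m2 <- voxelize(both, grid)
  expect_equal(nrow(m2$hexes), 2L)
  expect_equal(nrow(m2$nodes), 12L)
  expect_equal(nrow(m2$surface_faces), 10L)  # 12 cell faces - 2 shared
  expect_equal(sort(m2$surface_nodes), 1:12) # all nodes lie on the boundary
})

test_that("node-to-voxel correspondence is injective and geometrically tied", {
  model <- fixture_model()
  lin <- attachnet:::cell_index(model$node_to_voxel, model$grid$dims)
  expect_false(any(duplicated(lin)))          # one voxel per node
  expect_true(all(model$node_to_voxel >= 0))
  expect_true(all(sweep(model$node_to_voxel, 2, model$grid$dims, `<`)))
  # each node is the minimum corner of its voxel's cell
  corner <- sweep(model$node_to_voxel * model$grid$spacing, 2,
                  model$grid$origin, `+`)
  expect_lt(max(abs(corner - model$nodes)), 1e-12)
  # every surface node's voxel touches the node, and every kept cell's
  # minimum corner node maps back to exactly that cell
  cell_min_corner_nodes <- match(
    attachnet:::cell_index(model$node_to_voxel, model$grid$dims),
    model$kept_cells)
  expect_gt(sum(!is.na(cell_min_corner_nodes)), 0)
})

test_that("signed distance field matches analytics and a brute-force oracle", {
  sphere <- sphere_mesh(radius = 0.5, subdivisions = 3)
  grid <- regular_grid(origin = c(-0.7, -0.7, -0.7), spacing = 0.2,
                       dims = c(7, 7, 7))
  sdf <- signed_distance_field(sphere, grid)
  centers <- grid_centers(grid)
  r <- sqrt(rowSums(centers^2))
  # center voxel: distance = radius (inside, negative); use the analytic
  # value for the icosphere's mean radius
  ctr <- which.min(r)
  expect_lt(abs(sdf[ctr] + 0.5), 0.01)
  # sign: negative strictly inside, positive outside
  expect_true(all(sdf[r < 0.35] < 0))
  expect_true(all(sdf[r > 0.65] > 0))

  # brute-force triangle-distance oracle at 20 random voxels
  mesh <- fixture_mesh()
  g2 <- fit_grid(mesh, c(8, 8, 8))
  sdf2 <- signed_distance_field(mesh, g2)
  c2 <- grid_centers(g2)
  set.seed(42)
  for (v in sample(nrow(c2), 20)) {
    d_or <- min(vapply(seq_len(nrow(mesh$faces)), function(f)
      point_tri_dist_r(c2[v, ], mesh$vertices[mesh$faces[f, 1], ],
                       mesh$vertices[mesh$faces[f, 2], ],
                       mesh$vertices[mesh$faces[f, 3], ]), numeric(1)))
    expect_lt(abs(abs(sdf2[v]) - d_or), 2e-3 * max(d_or, 1e-3) + 1e-4)
  }

  # non-watertight mesh rejected
  open_mesh <- sphere
  open_mesh$faces <- open_mesh$faces[-1, ]
  expect_error(signed_distance_field(
    structure(open_mesh, class = "surface_mesh"), grid), "watertight")
})

test_that("voxel refinement does not lose interior coverage", {
  mesh <- sphere_mesh(radius = 0.5, subdivisions = 2)
  g1 <- fit_grid(mesh, c(6, 6, 6))
  g2 <- fit_grid(mesh, c(12, 12, 12))
  m1 <- voxelize(mesh, g1)
  m2 <- voxelize(mesh, g2)
  v1 <- length(m1$kept_cells) * g1$spacing^3
  v2 <- length(m2$kept_cells) * g2$spacing^3
  vol <- mesh_volume(mesh)
  # both cover the mesh volume; the finer grid hugs it more tightly
  expect_gte(v1, vol)
  expect_gte(v2, vol)
  expect_lte(v2, v1 + 1e-12)
})
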