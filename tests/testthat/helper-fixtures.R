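# Shared fixtures, built once per test run and cached.  All geometry is
# generated procedurally (no stored binaries).

.fix <- new.env(parent = emptyenv())

fixture_mesh <- function() {
  if (is.null(.fix$mesh))
    .fix$mesh <- generate_organ(organ_shape_spec(seed = 3L), n_faces = 1280)
  .fix$mesh
}

fixture_model <- function() {
  if (is.null(.fix$model))
    .fix$model <- voxelize(fixture_mesh(), fit_grid(fixture_mesh(),
                                                    c(12L, 10L, 8L)))
  .fix$model
}

# a small F=3 dataset shared by encoding / network / evaluation tests
fixture_dataset <- function() {
  if (is.null(.fix$ds))
    .fix$ds <- generate_dataset(fixture_model(), n_samples = 6, frames = 3,
                                seed = 11L)
  .fix$ds
}

# unit-cube surface mesh (2 triangles per face, outward orientation)
unit_cube_mesh <- function(scale = 1, center = c(0.5, 0.5, 0.5) * scale) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * scale
  v <- sweep(v, 2, c(0.5, 0.5, 0.5) * scale - center, `-`)
  # vertices: index = 1 + x + 2y + 4z
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(
    quad(1, 3, 4, 2),  # z = 0, normal -z
    quad(5, 6, 8, 7),  # z = 1, normal +z
    quad(1, 2, 6, 5),  # y = 0, normal -y
    quad(3, 7, 8, 4),  # y = 1, normal +y
    quad(1, 5, 7, 3),  # x = 0, normal -x
    quad(2, 4, 8, 6))  # x = 1, normal +x
  surface_mesh(v, f)
}

# icosphere mesh of given radius (watertight by construction)
sphere_mesh <- function(radius = 0.5, center = c(0, 0, 0), subdivisions = 2) {
  ico <- attachnet:::icosphere(subdivisions)
  surface_mesh(sweep(ico$vertices * radius, 2, center, `+`), ico$faces)
}

# independent R point-triangle distance (for SDF oracle)
point_tri_dist_r <- function(p, a, b, c) {
  # dense sampling of the triangle in barycentric coordinates
  n <- 60
  gr <- expand.grid(u = seq(0, 1, length.out = n), v = seq(0, 1, length.out = n))
  gr <- gr[gr$u + gr$v <= 1, ]
  pts <- outer(1 - gr$u - gr$v, a) + outer(gr$u, b) + outer(gr$v, c)
  sqrt(min(rowSums(sweep(pts, 2, p, `-`)^2)))
}

# independent inside test: ray-casting parity along +x
inside_ray_parity <- function(p, V, F) {
  crossings <- 0
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c <- V[F[f, 3], ]
    # solve p + t e_x = (1-u-v) a + u b + v c
    M <- cbind(c(-1, 0, 0), b - a, c - a)
    if (abs(det(M)) < 1e-14) next
    s <- solve(M, p - a)
    t <- s[1]; u <- s[2]; v <- s[3]
    if (t > 1e-12 && u >= 0 && v >= 0 && u + v <= 1) crossings <- crossings + 1
  }
  crossings %% 2 == 1
}

# single-hex model spanning [0, s]^3: a small sphere strictly inside the
# central cell of a 3x3x3 grid keeps exactly that cell
single_hex_model <- function(s = 0.02) {
  grid <- regular_grid(origin = c(-s, -s, -s), spacing = s, dims = c(3, 3, 3))
  mesh <- sphere_mesh(radius = 0.4 * s, center = rep(s / 2, 3))
  voxelize(mesh, grid)
}
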