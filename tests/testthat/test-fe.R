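# Neo-Hookean hexahedral FE: material, element derivatives against finite
# differences, solver contracts and continuum-mechanics limits.

test_that("material derives the Lame parameters", {
  m <- material()
  expect_equal(m$E, 5000)
  expect_equal(m$nu, 0.48)
  expect_equal(m$mu, 5000 / (2 * 1.48), tolerance = 1e-12)
  expect_equal(m$lambda, 5000 * 0.48 / (1.48 * 0.04), tolerance = 1e-12)
  expect_error(material(poisson_ratio = 0.5))
  expect_error(material(young_modulus = -1))
})

ref_hex <- function(s = 0.02) {
  X <- attachnet:::HEX_CORNERS * s
  storage.mode(X) <- "double"
  X
}

test_that("element energy is zero at rest and forces match FD gradients", {
  mat <- material()
  X <- ref_hex()
  zero <- matrix(0, 8, 3)
  e0 <- element_energy_force_stiffness(X, zero, mat)
  expect_equal(e0$energy, 0, tolerance = 1e-14)
  expect_lt(max(abs(e0$force)), 1e-10)

  # random small perturbation; forces = dW/du by central differences
  set.seed(31)
  u <- matrix(rnorm(24, sd = 1e-3), 8, 3)
  el <- element_energy_force_stiffness(X, u, mat)
  h <- 1e-7
  fd <- numeric(24)
  for (k in 1:24) {
    up <- u; up[(k - 1) %% 8 + 1, (k - 1) %/% 8 + 1] <- NA  # guard
    up <- u; um <- u
    node <- (k - 1) %/% 3 + 1; comp <- (k - 1) %% 3 + 1
    up[node, comp] <- u[node, comp] + h
    um[node, comp] <- u[node, comp] - h
    fd[k] <- (element_energy_force_stiffness(X, up, mat)$energy -
                element_energy_force_stiffness(X, um, mat)$energy) / (2 * h)
  }
  expect_lt(max(abs(el$force - fd)) / max(abs(fd)), 1e-5)
})

test_that("element tangent matches the FD Jacobian of the forces and is symmetric", {
  mat <- material()
  X <- ref_hex()
  set.seed(32)
  u <- matrix(rnorm(24, sd = 1e-3), 8, 3)
  el <- element_energy_force_stiffness(X, u, mat)
  expect_lt(max(abs(el$K - t(el$K))) / max(abs(el$K)), 1e-10)
  h <- 1e-6
  Kfd <- matrix(0, 24, 24)
  for (k in 1:24) {
    node <- (k - 1) %/% 3 + 1; comp <- (k - 1) %% 3 + 1
    up <- u; um <- u
    up[node, comp] <- u[node, comp] + h
    um[node, comp] <- u[node, comp] - h
    Kfd[, k] <- (element_energy_force_stiffness(X, up, mat)$force -
                   element_energy_force_stiffness(X, um, mat)$force) / (2 * h)
  }
  expect_lt(max(abs(el$K - Kfd)) / max(abs(Kfd)), 1e-4)
})

test_that("inverted elements are flagged", {
  mat <- material()
  X <- ref_hex()
  u <- matrix(0, 8, 3)
  u[5:8, 3] <- -0.03  # fold the top face through the bottom (s = 0.02)
  el <- element_energy_force_stiffness(X, u, mat)
  expect_true(el$inverted)
})

test_that("zero loads give zero displacement immediately", {
  model <- fixture_model()
  bc <- boundary_conditions(fixed_nodes = model$surface_nodes[1:10])
  res <- solve_static(model, material(), bc)
  expect_true(res$converged)
  expect_lte(res$iterations, 1L)
  expect_equal(max(abs(res$displacements)), 0)
})

test_that("small-strain uniaxial traction matches linear elasticity", {
  s <- 0.02
  model <- single_hex_model(s)
  mat <- material()
  bot <- which(abs(model$nodes[, 3]) < 1e-12)
  top <- which(abs(model$nodes[, 3] - s) < 1e-12)
  # roller supports: bottom fixed in z; two extra dofs pin rigid motions
  # without constraining lateral contraction
  fixed_dofs <- c(3 * (bot - 1) + 3,
                  3 * (bot[1] - 1) + 1:2,   # corner (0,0,0): x and y
                  3 * (bot[2] - 1) + 2)     # corner (s,0,0): y
  strain <- 0.001
  sigma <- mat$E * strain
  Ftot <- sigma * s^2
  bc <- boundary_conditions(load_nodes = top,
                            load_forces = matrix(Ftot / 4, 4, 3) *
                              rep(c(0, 0, 1), each = 4),
                            fixed_dofs = fixed_dofs)
  res <- solve_static(model, mat, bc)
  expect_true(res$converged)
  tip <- mean(res$displacements[top, 3])
  expect_lt(abs(tip - strain * s) / (strain * s), 0.01)
  # lateral contraction: width change of the top face ~ -nu * strain * s
  lat <- -(mean(res$displacements[top, 1][model$nodes[top, 1] > s / 2]) -
             mean(res$displacements[top, 1][model$nodes[top, 1] < s / 2]))
  expect_lt(abs(lat / s - mat$nu * strain) / (mat$nu * strain), 0.1)
})

test_that("surface-displacement-driven solves are invariant to Young's modulus", {
  model <- fixture_model()
  sn <- model$surface_nodes
  z <- model$nodes[sn, 3]
  fixed <- sn[z < quantile(z, 0.2)]
  driven <- sn[z >= quantile(z, 0.85)]
  disp <- matrix(rep(c(0.004, 0, -0.006), each = length(driven)), ncol = 3)
  r1 <- register_deformation(model, material(5000, 0.48), fixed, driven,
                             model$nodes[driven, ] + disp)
  r2 <- register_deformation(model, material(10000, 0.48), fixed, driven,
                             model$nodes[driven, ] + disp)
  expect_true(r1$converged && r2$converged)
  expect_lt(max(abs(r1$displacements - r2$displacements)), 1e-7)
})

test_that("solutions are invariant under rigid translation of the rest mesh", {
  model <- fixture_model()
  sn <- model$surface_nodes
  z <- model$nodes[sn, 3]
  fixed <- sn[z < quantile(z, 0.25)]
  loaded <- sn[z >= quantile(z, 0.9)]
  bc <- boundary_conditions(fixed_nodes = fixed, load_nodes = loaded,
                            load_forces = matrix(rep(c(0.3, 0, 0.2) /
                                                       length(loaded),
                                                     each = length(loaded)),
                                                 ncol = 3))
  mat <- material()
  r1 <- solve_static(model, mat, bc)
  shifted <- model
  shifted$nodes <- sweep(model$nodes, 2, c(1, -2, 0.5), `+`)
  shifted$cache <- new.env(parent = emptyenv())
  r2 <- solve_static(shifted, mat, bc)
  expect_true(r1$converged && r2$converged)
  expect_lt(max(abs(r1$displacements - r2$displacements)), 1e-8)
})

test_that("global tangent is symmetric and constrained rows are eliminated", {
  model <- single_hex_model()
  mat <- material()
  set.seed(7)
  u <- rnorm(24) * 1e-3
  a <- attachnet:::cpp_assemble(model$nodes, model$hexes, u, mat$mu,
                                mat$lambda, 2L)
  K <- Matrix::sparseMatrix(i = a$ki, j = a$kj, x = a$kv, dims = c(24, 24))
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-8)
})

test_that("small-strain solution matches linear-elastic FE on the same mesh", {
  # linear FE oracle: K_lin = tangent at u = 0; u_lin = K^-1 f
  model <- fixture_model()
  mat <- material()
  sn <- model$surface_nodes
  z <- model$nodes[sn, 3]
  fixed <- sn[z < quantile(z, 0.25)]
  loaded <- sn[z >= quantile(z, 0.92)]
  f <- 0.02  # N total: produces < 0.5% strain
  bc <- boundary_conditions(fixed_nodes = fixed, load_nodes = loaded,
                            load_forces = matrix(rep(c(0, 0, -f) /
                                                       length(loaded),
                                                     each = length(loaded)),
                                                 ncol = 3))
  res <- solve_static(model, mat, bc)
  expect_true(res$converged)
  ndof <- 3 * nrow(model$nodes)
  a0 <- attachnet:::cpp_assemble(model$nodes, model$hexes, numeric(ndof),
                                 mat$mu, mat$lambda, 2L)
  K <- Matrix::sparseMatrix(i = a0$ki, j = a0$kj, x = a0$kv,
                            dims = c(ndof, ndof))
  ba <- attachnet:::bc_arrays(model, bc)
  free <- setdiff(seq_len(ndof), ba$cdof)
  u_lin <- numeric(ndof)
  u_lin[free] <- as.numeric(Matrix::solve(K[free, free], ba$f_ext[free]))
  u_nl <- as.vector(t(res$displacements))
  expect_lt(max(abs(u_nl - u_lin)) / max(abs(u_lin)), 0.02)
})

test_that("registration drives controls to their targets and rejects conflicts", {
  model <- fixture_model()
  mat <- material()
  sn <- model$surface_nodes
  att <- sn[1:30]
  ctl <- sn[60:75]
  # targets equal rest positions -> zero displacement
  r0 <- register_deformation(model, mat, att, ctl, model$nodes[ctl, ])
  expect_true(r0$converged)
  expect_lt(max(abs(r0$displacements)), 1e-10)
  # control targets are met exactly; attachments stay put
  tgt <- model$nodes[ctl, ] + matrix(rep(c(0.003, -0.002, 0.004),
                                         each = length(ctl)), ncol = 3)
  r1 <- register_deformation(model, mat, att, ctl, tgt)
  expect_true(r1$converged)
  expect_lt(max(abs(model$nodes[ctl, ] + r1$displacements[ctl, ] - tgt)), 1e-12)
  expect_equal(max(abs(r1$displacements[att, ])), 0)
  # overlap between controls and attachments is a conflict
  expect_error(register_deformation(model, mat, att, c(att[1], ctl),
                                    model$nodes[c(att[1], ctl), ]),
               "must not belong")
})

test_that("underconstrained loaded systems are refused", {
  model <- fixture_model()
  bc <- boundary_conditions(load_nodes = model$surface_nodes[1:5],
                            load_forces = matrix(0.1, 5, 3))
  expect_error(solve_static(model, material(), bc), "underconstrained")
})
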