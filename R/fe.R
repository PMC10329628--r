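# Static hyperelastic FE on the hexahedral model: compressible Neo-Hookean
# material, Dirichlet constraints by row/column elimination (exact
# satisfaction), incremental loading with Newton-Raphson and a backtracking
# line search.  Intended scale is a desk-size model (<= ~10k DOFs) solved
# with a direct sparse factorization.

#' Hyperelastic material parameters
#'
#' Compressible Neo-Hookean solid with strain energy
#' W = mu/2 (I1 - 3) - mu ln J + lambda/2 (ln J)^2. The defaults (E = 5000
#' Pa, nu = 0.48) describe near-incompressible liver parenchyma.
#'
#' @param young_modulus Young's modulus E in Pa.
#' @param poisson_ratio Poisson's ratio in [0, 0.5).
#' @return object of class \code{material} with derived Lame parameters
#'   \code{mu} and \code{lambda}.
#' @export
material <- function(young_modulus = 5000, poisson_ratio = 0.48) {
  stopifnot(young_modulus > 0, poisson_ratio >= 0, poisson_ratio < 0.5)
  m <- list(E = young_modulus, nu = poisson_ratio,
            mu = young_modulus / (2 * (1 + poisson_ratio)),
            lambda = young_modulus * poisson_ratio /
              ((1 + poisson_ratio) * (1 - 2 * poisson_ratio)))
  class(m) <- "material"
  m
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("material: E = %g Pa, nu = %g (mu = %.2f, lambda = %.2f Pa)\n",
              x$E, x$nu, x$mu, x$lambda))
  invisible(x)
}

#' Dirichlet and load boundary conditions
#'
#' @param fixed_nodes node indices held at zero displacement (attachments).
#' @param prescribed_nodes,prescribed_disp nodes driven to target
#'   displacements (matrix n x 3, meters); used by the registration solve.
#' @param load_nodes,load_forces nodes carrying external forces (n x 3, N).
#' @param fixed_dofs additional single-component constraints as global DOF
#'   indices 3*(node-1)+component (component 1..3), e.g. a roller support
#'   fixing only the z component of a face.
#' @return object of class \code{boundary_conditions}.
#' @export
boundary_conditions <- function(fixed_nodes = integer(0),
                                prescribed_nodes = integer(0),
                                prescribed_disp = NULL,
                                load_nodes = integer(0), load_forces = NULL,
                                fixed_dofs = integer(0)) {
  fixed_nodes <- as.integer(fixed_nodes)
  fixed_dofs <- as.integer(fixed_dofs)
  prescribed_nodes <- as.integer(prescribed_nodes)
  load_nodes <- as.integer(load_nodes)
  if (length(prescribed_nodes)) {
    prescribed_disp <- as.matrix(prescribed_disp)
    stopifnot(nrow(prescribed_disp) == length(prescribed_nodes),
              ncol(prescribed_disp) == 3)
  }
  if (length(load_nodes)) {
    load_forces <- as.matrix(load_forces)
    stopifnot(nrow(load_forces) == length(load_nodes), ncol(load_forces) == 3)
  }
  if (length(intersect(fixed_nodes, prescribed_nodes)) ||
      length(intersect(fixed_nodes, load_nodes)) ||
      length(intersect(prescribed_nodes, load_nodes)))
    stop("fixed, prescribed and loaded node sets must be pairwise disjoint")
  bc <- list(fixed_nodes = fixed_nodes, prescribed_nodes = prescribed_nodes,
             prescribed_disp = prescribed_disp, load_nodes = load_nodes,
             load_forces = load_forces, fixed_dofs = fixed_dofs)
  class(bc) <- "boundary_conditions"
  bc
}

#' Single-element Neo-Hookean energy, internal force and tangent
#'
#' 2x2x2 Gauss quadrature on a trilinear hexahedron. Forces are the gradient
#' of the strain energy with respect to the nodal displacements; the tangent
#' is its (symmetric) Hessian.
#'
#' @param X 8 x 3 rest nodal positions (VTK ordering).
#' @param u 8 x 3 nodal displacements.
#' @param mat a \code{material}.
#' @return list(energy, force (24), K (24 x 24), inverted).
#' @export
element_energy_force_stiffness <- function(X, u, mat) {
  stopifnot(inherits(mat, "material"))
  cpp_hex_efk(as.matrix(X), as.matrix(u), mat$mu, mat$lambda)
}

# Precomputed CSC sparsity of the global tangent for a hex model: maps the
# fixed element-slot ordering of cpp_assemble_slots onto the x slot of a
# dgCMatrix, so per-iteration assembly is a scatter-add.  Cached in the
# model's environment.
stiffness_pattern <- function(model) {
  cache <- model$cache
  if (!is.null(cache$pattern)) return(cache$pattern)
  H <- model$hexes
  ndof <- 3L * nrow(model$nodes)
  A <- rep(1:8, each = 72)              # slot order ((a*8+b)*3+i)*3+j
  B <- rep(rep(1:8, each = 9), times = 8)
  I <- rep(rep(1:3, each = 3), times = 64)
  J <- rep(1:3, times = 192)
  ki <- as.vector(t(sweep(3L * (H[, A, drop = FALSE] - 1L), 2, I, `+`)))
  kj <- as.vector(t(sweep(3L * (H[, B, drop = FALSE] - 1L), 2, J, `+`)))
  o <- order(kj, ki)
  kio <- ki[o]; kjo <- kj[o]
  n <- length(kio)
  new_entry <- c(TRUE, kio[-1] != kio[-n] | kjo[-1] != kjo[-n])
  xidx <- cumsum(new_entry)
  map <- integer(n); map[o] <- xidx
  pat <- list(i = kio[new_entry], p = c(0L, cumsum(tabulate(kjo[new_entry], nbins = ndof))),
              map = map, nnz = xidx[n], ndof = ndof)
  cache$pattern <- pat
  pat
}

# full 3N external force vector and constrained-DOF bookkeeping
bc_arrays <- function(model, bcs) {
  n <- nrow(model$nodes)
  if (max(c(bcs$fixed_nodes, bcs$prescribed_nodes, bcs$load_nodes, 0L)) > n)
    stop("boundary condition node index out of range")
  if (length(bcs$fixed_dofs) &&
      (min(bcs$fixed_dofs) < 1L || max(bcs$fixed_dofs) > 3L * n))
    stop("fixed_dofs index out of range")
  f_ext <- numeric(3 * n)
  if (length(bcs$load_nodes))
    for (k in seq_along(bcs$load_nodes))
      f_ext[3 * (bcs$load_nodes[k] - 1) + 1:3] <- bcs$load_forces[k, ]
  cn <- c(bcs$fixed_nodes, bcs$prescribed_nodes)
  cdof <- as.vector(t(outer(3 * (cn - 1), 1:3, `+`)))
  ctarget <- rbind(matrix(0, length(bcs$fixed_nodes), 3),
                   if (length(bcs$prescribed_nodes)) bcs$prescribed_disp)
  ctarget <- if (length(cn)) as.vector(t(ctarget)) else numeric(0)
  extra <- setdiff(bcs$fixed_dofs, cdof)
  list(f_ext = f_ext, cdof = c(cdof, extra),
       ctarget = c(ctarget, numeric(length(extra))))
}

#' Static Newton-Raphson solve of the hexahedral model
#'
#' Applies the loads and Dirichlet targets in \code{n_steps} equal
#' increments; within each increment Newton iterations with a backtracking
#' line search on the total potential energy run until the free-DOF residual
#' drops below \code{tol} times a characteristic force (max of the external
#' load norm and lambda * spacing^2). Element inversion or line-search
#' failure triggers increment halving; if halving is exhausted the result is
#' flagged non-converged (such samples are discarded by the dataset filter).
#'
#' @param model a \code{hex_model}.
#' @param mat a \code{material}.
#' @param bcs \code{boundary_conditions}; must constrain all rigid motions.
#' @param n_steps number of load increments (default 5).
#' @param tol relative residual tolerance (default 1e-6).
#' @param max_iter Newton iterations per increment (default 25).
#' @param max_halvings increment halvings allowed on failure (default 4).
#' @param max_total_iter overall Newton iteration budget across all
#'   increments and retries (default Inf); exceeded budget returns
#'   \code{converged = FALSE}. Dataset generation uses a finite budget so
#'   hopeless samples fail fast.
#' @return object of class \code{solve_result}: \code{displacements}
#'   (n x 3, m), \code{converged}, \code{iterations}, \code{residual_norm}.
#' @export
solve_static <- function(model, mat, bcs, n_steps = 5L, tol = 1e-6,
                         max_iter = 25L, max_halvings = 4L,
                         max_total_iter = Inf) {
  stopifnot(inherits(model, "hex_model"), inherits(mat, "material"),
            inherits(bcs, "boundary_conditions"))
  n <- nrow(model$nodes)
  ndof <- 3L * n
  ba <- bc_arrays(model, bcs)
  if (length(ba$cdof) == 0L && sqrt(sum(ba$f_ext^2)) > 0)
    stop("underconstrained: no Dirichlet constraints to remove rigid motions")
  free <- setdiff(seq_len(ndof), ba$cdof)
  fscale <- max(sqrt(sum(ba$f_ext^2)), mat$lambda * model$grid$spacing^2)

  u <- numeric(ndof)
  total_iters <- 0L
  res_norm <- NA_real_
  alpha <- 0          # completed load fraction
  dalpha <- 1 / n_steps
  halvings <- 0L

  pat <- stiffness_pattern(model)
  chol_cache <- NULL
  potential <- function(u, f_ext) {
    a <- cpp_assemble(model$nodes, model$hexes, u, mat$mu, mat$lambda, 0L)
    if (isTRUE(a$inverted)) return(Inf)
    a$energy - sum(f_ext * u)
  }

  while (alpha < 1 - 1e-12) {
    step_frac <- min(1, alpha + dalpha)
    u_try <- u
    if (length(ba$cdof)) u_try[ba$cdof] <- step_frac * ba$ctarget
    f_s <- step_frac * ba$f_ext
    ok <- TRUE
    iters <- 0L
    r_prev <- Inf
    force_refactor <- FALSE
    retried <- FALSE
    repeat {
      a <- cpp_assemble(model$nodes, model$hexes, u_try, mat$mu, mat$lambda, 1L)
      if (isTRUE(a$inverted)) { ok <- FALSE; break }
      r <- a$grad - f_s
      res_norm <- sqrt(sum(r[free]^2))
      if (res_norm <= tol * fscale) break
      if (iters >= max_iter) { ok <- FALSE; break }
      if (total_iters >= max_total_iter) {
        return(structure(list(displacements = matrix(u, n, 3, byrow = TRUE),
                              converged = FALSE, iterations = total_iters,
                              residual_norm = res_norm),
                         class = "solve_result"))
      }
      # modified Newton: the factored tangent is reused across iterations and
      # refreshed when the residual stops contracting fast enough (a frozen
      # iteration costs ~1/8 of a refactor, so slowish contraction is fine)
      if (force_refactor || is.null(chol_cache) || res_norm > 0.6 * r_prev) {
        as_ <- cpp_assemble_slots(model$nodes, model$hexes, u_try,
                                  mat$mu, mat$lambda)
        if (isTRUE(as_$inverted)) { ok <- FALSE; break }
        xv <- cpp_scatter_add(as_$kv, pat$map, pat$nnz)
        K <- Matrix::sparseMatrix(i = pat$i, p = pat$p, x = xv,
                                  dims = c(ndof, ndof))
        Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
        # symmetric tangent: sparse Cholesky (symbolic reused), LU fallback
        # simplicial LDL': factors indefinite tangents too (signed D), so the
        # failure path — which leaks CHOLMOD workspace — is almost never hit;
        # sparse LU remains as a last resort for zero pivots
        fac <- suppressWarnings(tryCatch({
          chol_cache <- if (is.null(chol_cache))
            Matrix::Cholesky(Kff, LDL = TRUE, perm = TRUE)
          else Matrix::update(chol_cache, Kff)
          TRUE
        }, error = function(e) FALSE))
        if (!fac) {
          du_lu <- tryCatch(
            as.numeric(Matrix::solve(K[free, free, drop = FALSE], -r[free])),
            error = function(e2) stop("underconstrained or singular stiffness: ",
                                      conditionMessage(e2)))
          chol_cache <- NULL
        }
        force_refactor <- FALSE
        fresh_factor <- TRUE
      } else {
        fac <- TRUE
        fresh_factor <- FALSE
      }
      du <- if (fac) as.numeric(Matrix::solve(chol_cache, -r[free])) else du_lu
      # backtracking line search on the potential energy
      p0 <- a$energy - sum(f_s * u_try)
      gdu <- sum(r[free] * du)
      t_ls <- 1
      accepted <- FALSE
      for (ls in 1:12) {
        u_new <- u_try
        u_new[free] <- u_try[free] + t_ls * du
        p1 <- potential(u_new, f_s)
        if (is.finite(p1) && p1 <= p0 + 1e-4 * t_ls * gdu) {
          u_try <- u_new; accepted <- TRUE; break
        }
        t_ls <- t_ls / 2
      }
      if (!accepted && !fresh_factor && !retried) {
        # stale tangent gave a bad direction; refresh and retry once
        force_refactor <- TRUE
        retried <- TRUE
        next
      }
      retried <- FALSE
      iters <- iters + 1L
      total_iters <- total_iters + 1L
      if (!accepted) { ok <- FALSE; break }
      r_prev <- res_norm
    }
    if (ok) {
      u <- u_try
      alpha <- step_frac
    } else {
      halvings <- halvings + 1L
      dalpha <- dalpha / 2
      if (halvings > max_halvings) {
        return(structure(list(displacements = matrix(u, n, 3, byrow = TRUE),
                              converged = FALSE, iterations = total_iters,
                              residual_norm = res_norm),
                         class = "solve_result"))
      }
    }
  }
  structure(list(displacements = matrix(u, n, 3, byrow = TRUE),
                 converged = TRUE, iterations = total_iters,
                 residual_norm = res_norm),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("solve_result: %s after %d Newton iterations (residual %.3e)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual_norm))
  cat(sprintf("  max nodal displacement: %.4f m\n",
              max(sqrt(rowSums(x$displacements^2)))))
  invisible(x)
}

#' FE registration under a candidate attachment set
#'
#' Fixes the candidate attachment nodes at zero displacement, drives the
#' control nodes to their target positions as prescribed displacements and
#' solves for the remaining free nodes, returning the deformed state used to
#' score candidate boundary conditions against held-out points.
#'
#' @param model a \code{hex_model}.
#' @param mat a \code{material}.
#' @param attachments candidate attachment node indices (may be empty).
#' @param control_nodes nodes with known targets; must be disjoint from
#'   \code{attachments}.
#' @param control_targets matrix (length(control_nodes) x 3) of target
#'   positions (m) in the deformed state.
#' @param ... passed to \code{\link{solve_static}}.
#' @return a \code{solve_result}.
#' @export
register_deformation <- function(model, mat, attachments, control_nodes,
                                 control_targets, ...) {
  attachments <- as.integer(attachments)
  control_nodes <- as.integer(control_nodes)
  if (length(intersect(attachments, control_nodes)))
    stop("control nodes must not belong to the candidate attachment set")
  disp <- as.matrix(control_targets) - model$nodes[control_nodes, , drop = FALSE]
  bcs <- boundary_conditions(fixed_nodes = attachments,
                             prescribed_nodes = control_nodes,
                             prescribed_disp = disp)
  solve_static(model, mat, bcs, ...)
}
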