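# Procedural liver-like organ surfaces: an ellipsoid envelope perturbed by
# band-limited spherical-harmonic noise and a few Gaussian lobes, remeshed on
# an icosphere so the result is watertight and outward-oriented by
# construction.  Stands in for a patient surface segmented from CT.

#' Specify a procedural organ shape
#'
#' @param base_radii three ellipsoid semi-axes in meters; the default
#'   (0.14, 0.10, 0.08) approximates an adult liver envelope.
#' @param lobe_count number of Gaussian lobe bumps.
#' @param bump_amplitude maximum radial perturbation as a fraction of the
#'   local radius, in [0, 0.5].
#' @param smoothness spherical-harmonic band limit of the surface noise.
#' @param seed RNG seed; a fixed seed gives a bitwise-identical mesh.
#' @return an object of class \code{organ_shape_spec}.
#' @export
organ_shape_spec <- function(base_radii = c(0.14, 0.10, 0.08), lobe_count = 2L,
                             bump_amplitude = 0.15, smoothness = 6L, seed = 1L) {
  stopifnot(length(base_radii) == 3, all(base_radii > 0),
            bump_amplitude >= 0, bump_amplitude <= 0.5, lobe_count >= 0)
  spec <- list(base_radii = as.numeric(base_radii),
               lobe_count = as.integer(lobe_count),
               bump_amplitude = as.numeric(bump_amplitude),
               smoothness = as.integer(smoothness), seed = as.integer(seed))
  class(spec) <- "organ_shape_spec"
  spec
}

# unit icosphere: icosahedron + n subdivisions (20 * 4^n faces)
icosphere <- function(subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- p
      midcache[[key]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  list(vertices = v, faces = f)
}

# real spherical harmonics sum up to band limit L with given coefficients;
# dirs: unit direction matrix
sh_field <- function(dirs, coefs, L) {
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  out <- numeric(nrow(dirs))
  ci <- 1L
  for (l in 2:L) {
    P <- t(legendre_assoc(l, ct))  # n x (l+1), columns m = 0..l
    norm0 <- sqrt((2 * l + 1) / (4 * pi))
    out <- out + coefs[ci] * norm0 * P[, 1]; ci <- ci + 1L
    for (m in 1:l) {
      nm <- sqrt(2) * sqrt((2 * l + 1) / (4 * pi) *
                             exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      out <- out + coefs[ci] * nm * P[, m + 1] * cos(m * phi); ci <- ci + 1L
      out <- out + coefs[ci] * nm * P[, m + 1] * sin(m * phi); ci <- ci + 1L
    }
  }
  out
}

# associated Legendre P_l^m(x) for m = 0..l (Condon-Shortley phase),
# returned as (l+1) x length(x)
legendre_assoc <- function(l, x) {
  n <- length(x)
  somx2 <- sqrt(pmax(0, 1 - x^2))
  out <- matrix(0, l + 1, n)
  for (m in 0:l) {
    pmm <- rep(1, n)
    if (m > 0) for (k in 1:m) pmm <- pmm * (-(2 * k - 1)) * somx2
    if (m == l) { out[m + 1, ] <- pmm; next }
    pmmp1 <- x * (2 * m + 1) * pmm
    if (m == l - 1) { out[m + 1, ] <- pmmp1; next }
    prev2 <- pmm; prev1 <- pmmp1
    for (ll in (m + 2):l) {
      pll <- (x * (2 * ll - 1) * prev1 - (ll + m - 1) * prev2) / (ll - m)
      prev2 <- prev1; prev1 <- pll
    }
    out[m + 1, ] <- prev1
  }
  out
}

#' Generate a watertight liver-like surface mesh
#'
#' Evaluates a radial perturbation field (spherical-harmonic noise plus
#' \code{lobe_count} Gaussian bumps, scaled so its maximum equals
#' \code{bump_amplitude}) on an icosphere and maps it through the ellipsoid
#' semi-axes. The mesh is star-shaped around the origin, hence watertight and
#' outward-oriented by construction.
#'
#' @param spec an \code{\link{organ_shape_spec}}.
#' @param n_faces approximate face count (rounded to an icosphere level).
#' @return a \code{surface_mesh}.
#' @export
generate_organ <- function(spec = organ_shape_spec(), n_faces = 1280L) {
  stopifnot(inherits(spec, "organ_shape_spec"))
  subdiv <- max(1L, ceiling(log(n_faces / 20) / log(4)))
  ico <- icosphere(subdiv)
  dirs <- ico$vertices
  L <- spec$smoothness
  if (spec$bump_amplitude > 0 && L < 2L) {
    warning("spherical-harmonic band limit too low to resolve lobes; clamped to 2")
    L <- 2L
  }
  perturb <- numeric(nrow(dirs))
  if (spec$bump_amplitude > 0) {
    with_seed(spec$seed, {
      ncoef <- sum(2 * (2:L) + 1)
      coefs <- stats::rnorm(ncoef) / (1 + rep(2:L, times = 2 * (2:L) + 1))
      p <- sh_field(dirs, coefs, L)
      if (spec$lobe_count > 0) {
        u <- matrix(stats::rnorm(3 * spec$lobe_count), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        width <- 0.6  # radians
        for (k in seq_len(spec$lobe_count)) {
          ang <- acos(pmin(1, pmax(-1, dirs %*% u[k, ])))
          p <- p + exp(-ang^2 / (2 * width^2))
        }
      }
      perturb <- p / max(abs(p))
    })
  }
  r <- 1 + spec$bump_amplitude * perturb
  verts <- dirs * r
  verts <- sweep(verts, 2, spec$base_radii, `*`)
  surface_mesh(verts, ico$faces)
}
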