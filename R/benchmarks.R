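# Verification benchmarks for the numerical core: Dirichlet patch test,
# uniaxial block compression, and a rigid sphere pressed into an elastic
# block against the Hertz closed form.

#' Solve a linear system with Dirichlet conditions
#'
#' Partitioned solve of K u = f with prescribed values on fixed dofs.
#'
#' @param K sparse symmetric stiffness.
#' @param f force vector.
#' @param fixed_dofs integer dof indices.
#' @param fixed_vals prescribed values (recycled).
#' @return full displacement vector.
#' @export
fe_linear_solve <- function(K, f, fixed_dofs, fixed_vals = 0) {
  n <- nrow(K)
  fixed_vals <- rep_len(fixed_vals, length(fixed_dofs))
  free <- setdiff(seq_len(n), fixed_dofs)
  uf <- numeric(n)
  uf[fixed_dofs] <- fixed_vals
  rhs <- f[free] - as.vector(K[free, fixed_dofs, drop = FALSE] %*% fixed_vals)
  uf[free] <- as.vector(Matrix::solve(K[free, free], rhs, sparse = TRUE))
  uf
}

#' Constant-strain patch test
#'
#' Applies the linear displacement field of a prescribed constant strain to
#' every boundary node of a single-material tet mesh, solves for the interior
#' and checks that the recovered stress is the constant closed-form value in
#' every element.
#'
#' @param n grid divisions of the unit-cube mesh.
#' @param E,nu material constants.
#' @param strain Voigt strain to impose.
#' @return list: max relative stress deviation `rel_error`, the expected
#'   stress, pass flag at 1e-8.
#' @export
benchmark_patch_test <- function(n = 3L, E = 15, nu = 0.3,
                                 strain = c(0.01, -0.004, 0.002,
                                            0.006, -0.003, 0.005)) {
  xs <- seq(0, 1, length.out = n + 1L)
  mesh <- box_mesh(xs, xs, xs, region = "block")
  mats <- list(block = isotropic_elastic(E, nu))
  K <- fe_stiffness(mesh, mats)
  A <- rbind(c(strain[1L], strain[6L] / 2, strain[5L] / 2),
             c(strain[6L] / 2, strain[2L], strain[4L] / 2),
             c(strain[5L] / 2, strain[4L] / 2, strain[3L]))
  nd <- mesh$nodes
  on_bnd <- which(apply(nd, 1L, function(p) any(abs(p) < 1e-12 | abs(p - 1) < 1e-12)))
  ub <- nd[on_bnd, , drop = FALSE] %*% t(A)
  fixed <- as.vector(vapply(on_bnd, function(v) 3L * (v - 1L) + 1:3, integer(3L)))
  u <- fe_linear_solve(K, numeric(nrow(K)), fixed, as.vector(t(ub)))
  fld <- recover_stresses(mesh, u, mats)
  expected <- as.vector(stiffness_isotropic(mats$block) %*% strain)
  dev <- sweep(fld$stress, 2L, expected)
  rel <- max(abs(dev)) / max(abs(expected))
  list(rel_error = rel, expected = expected, pass = rel <= 1e-8)
}

#' Uniaxial block compression benchmark
#'
#' Block with base fixed vertically and uniform pressure on top; for nu = 0
#' the axial strain is p/E exactly in the continuum limit.
#'
#' @param p pressure, MPa.
#' @param E modulus, MPa.
#' @param n grid divisions.
#' @return list: computed axial strain, closed form p/E, relative error.
#' @export
benchmark_uniaxial <- function(p = 1, E = 15, n = 3L) {
  xs <- seq(0, 10, length.out = n + 1L)
  zs <- seq(0, 5, length.out = n + 1L)
  mesh <- box_mesh(xs, xs, zs, region = "block")
  mats <- list(block = isotropic_elastic(E, 0))
  K <- fe_stiffness(mesh, mats)
  nd <- mesh$nodes
  bot <- which(abs(nd[, 3L]) < 1e-12)
  top_f <- surface_facets_z(mesh, max(nd[, 3L]))
  areas <- tributary_areas(nd, top_f)
  f <- numeric(nrow(K))
  f[3L * (seq_len(nrow(nd)) - 1L) + 3L] <- -p * areas
  # fix base in z; pin lateral rigid modes at one corner line
  fixed <- 3L * (bot - 1L) + 3L
  corner <- which(abs(nd[, 1L]) < 1e-12 & abs(nd[, 2L]) < 1e-12)
  fixed <- c(fixed, 3L * (corner - 1L) + 1L, 3L * (corner - 1L) + 2L)
  u <- fe_linear_solve(K, f, fixed, 0)
  uz_top <- mean(u[3L * (which(abs(nd[, 3L] - max(nd[, 3L])) < 1e-12) - 1L) + 3L])
  strain <- -uz_top / max(nd[, 3L])
  list(strain = strain, closed_form = p / E,
       rel_error = abs(strain - p / E) / (p / E))
}

# boundary facets of a box mesh lying on plane z = z0
surface_facets_z <- function(mesh, z0) {
  faces <- tet_faces(mesh$tets)
  key <- face_key(faces)
  cnt <- table(key)
  bf <- faces[cnt[key] == 1L, , drop = FALSE]
  onz <- abs(mesh$nodes[, 3L] - z0) < 1e-9
  bf[onz[bf[, 1L]] & onz[bf[, 2L]] & onz[bf[, 3L]], , drop = FALSE]
}

# graded symmetric 1-D grid: spacing h_fine inside [-r_fine, r_fine],
# geometrically coarsening to the half-width L
graded_axis <- function(L, r_fine, h_fine, ratio = 1.35) {
  xs <- seq(0, r_fine, by = h_fine)
  h <- h_fine
  while (xs[length(xs)] < L) {
    h <- h * ratio
    xs <- c(xs, min(L, xs[length(xs)] + h))
  }
  sort(unique(c(-xs, xs)))
}

#' Rigid sphere on elastic block (Hertz) benchmark
#'
#' A rigid sphere of radius R is pressed with force F into an E, nu elastic
#' block (base fixed); the peak contact pressure is compared with the Hertz
#' closed form p0 = (6 F E*^2 / (pi^3 R^2))^(1/3), E* = E/(1-nu^2). Contact
#' uses the same penalty node-to-surface machinery as the joint solver, with
#' the sphere as a one-dof rigid body.
#'
#' @param F force, N.
#' @param R sphere radius, mm.
#' @param E,nu block material.
#' @param h_fine mesh size in the contact zone, mm.
#' @param block_half,block_depth block half-width and depth, mm.
#' @param penalty_factor penalty scale.
#' @return list: FE peak pressure, Hertz p0, relative error, contact radius.
#' @export
benchmark_hertz <- function(F = 100, R = 20, E = 15, nu = 0.3,
                            h_fine = 1.5, block_half = 24, block_depth = 16,
                            penalty_factor = 100) {
  Estar <- E / (1 - nu^2)
  a_hertz <- (3 * F * R / (4 * Estar))^(1 / 3)
  p0 <- (6 * F * Estar^2 / (pi^3 * R^2))^(1 / 3)
  # quarter-symmetry model: x >= 0, y >= 0 with symmetry-plane conditions
  ax <- graded_axis(block_half, 1.6 * a_hertz, h_fine)
  xs <- ax[ax >= 0]
  az <- graded_axis(block_depth, 3, 0.75 * h_fine)
  zs <- -rev(az[az >= 0])
  mesh <- box_mesh(xs, xs, zs, region = "block")
  mats <- list(block = isotropic_elastic(E, nu))
  K <- fe_stiffness(mesh, mats)
  nd <- mesh$nodes
  n_nodes <- nrow(nd)
  ndof <- 3L * n_nodes + 1L              # + sphere vertical dof
  bot <- which(abs(nd[, 3L] + block_depth) < 1e-9)
  fixed <- as.vector(vapply(bot, function(v) 3L * (v - 1L) + 1:3, integer(3L)))
  fixed <- c(fixed, 3L * (which(abs(nd[, 1L]) < 1e-9) - 1L) + 1L,  # x-symmetry
             3L * (which(abs(nd[, 2L]) < 1e-9) - 1L) + 2L)         # y-symmetry
  fixed <- sort(unique(fixed))
  top_nodes <- which(abs(nd[, 3L]) < 1e-9 &
                     nd[, 1L]^2 + nd[, 2L]^2 < (2.2 * a_hertz)^2)
  top_f <- surface_facets_z(mesh, 0)
  areas <- tributary_areas(nd, top_f)
  ctr0 <- c(0, 0, R)
  k_area <- penalty_factor * E / h_fine
  cons <- lapply(top_nodes, function(v) {
    x <- nd[v, ]
    d <- x - ctr0
    n <- d / sqrt(sum(d^2))
    list(dofs = c(3L * (v - 1L) + 1:3, ndof),
         coef = c(n, -n[3L]),
         g0 = sqrt(sum(d^2)) - R,
         k = k_area * areas[v], area = areas[v])
  })
  ncon <- length(cons)
  Kfull <- Matrix::bdiag(K, Matrix::Matrix(1e-4, 1L, 1L))  # weak grounding
  f <- numeric(ndof); f[ndof] <- -F / 4   # quarter model carries F/4
  free <- setdiff(seq_len(ndof), fixed)
  # pre-reduce to free dofs once
  Kfree <- Kfull[free, free]
  D <- Matrix::sparseMatrix(
    i = rep(seq_len(ncon), each = 4L),
    j = unlist(lapply(cons, `[[`, "dofs")),
    x = unlist(lapply(cons, `[[`, "coef")), dims = c(ncon, ndof))
  Dfree <- D[, free, drop = FALSE]
  g0 <- vapply(cons, `[[`, 0, "g0")
  kvec <- vapply(cons, `[[`, 0, "k")
  ffree <- f[free]
  u <- numeric(length(free))
  active_prev <- rep(FALSE, ncon)
  rn <- Inf
  for (it in 1:60) {
    gaps <- g0 + as.vector(Dfree %*% u)
    active <- gaps <= 0
    r <- ffree - as.vector(Kfree %*% u)
    if (any(active))
      r <- r - as.vector(Matrix::t(Dfree[active, , drop = FALSE]) %*%
                         (kvec[active] * gaps[active]))
    rn <- sqrt(sum(r^2)) / (F / 4)
    if (rn < 1e-8 && identical(active, active_prev) && it > 1L) break
    Ka <- Kfree
    if (any(active)) {
      Da <- Dfree[active, , drop = FALSE]
      Ka <- Ka + Matrix::forceSymmetric(Matrix::t(Da) %*% (kvec[active] * Da))
    }
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Ka), LDL = FALSE, perm = TRUE)
    u <- u + as.vector(Matrix::solve(ch, r, system = "A"))
    active_prev <- active
  }
  gaps <- g0 + as.vector(Dfree %*% u)
  pen <- pmax(0, -gaps)
  pressure <- kvec * pen / vapply(cons, `[[`, 0, "area")
  rcon <- sqrt(nd[top_nodes, 1L]^2 + nd[top_nodes, 2L]^2)
  p_peak <- max(pressure)
  list(p_peak = p_peak, p0_hertz = p0,
       rel_error = abs(p_peak - p0) / p0,
       a_hertz = a_hertz,
       a_fe = if (any(pen > 1e-9)) max(rcon[pen > 1e-9]) else 0,
       total_force = 4 * sum(kvec * pen),
       n_nodes = n_nodes,
       iterations = it, residual = rn)
}

#' Run the verification benchmark suite
#'
#' Patch test, single-element oracle, stress-invariant oracle on random
#' tensors, uniaxial compression and the Hertz contact benchmark, each with
#' its tolerance.
#'
#' @param hertz include the (slower) Hertz benchmark.
#' @param seed seed for the random-tensor oracle.
#' @return data.frame with benchmark, value, tolerance and pass flag.
#' @export
verify_suite <- function(hertz = TRUE, seed = 1L) {
  rows <- list()
  pt <- benchmark_patch_test()
  rows$patch <- data.frame(benchmark = "patch_test", value = pt$rel_error,
                           tolerance = 1e-8, pass = pt$pass)
  ua <- benchmark_uniaxial()
  rows$uni <- data.frame(benchmark = "uniaxial_block", value = ua$rel_error,
                         tolerance = 1e-2, pass = ua$rel_error <= 1e-2)
  # eigenvalue oracle on random symmetric tensors
  set.seed(seed)
  S <- matrix(stats::rnorm(6000), ncol = 6L)
  pr <- principal_stresses(S)
  ev <- t(apply(S, 1L, function(s) {
    M <- matrix(c(s[1L], s[6L], s[5L],
                  s[6L], s[2L], s[4L],
                  s[5L], s[4L], s[3L]), 3L)
    sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }))
  edev <- max(abs(pr - ev))
  rows$eig <- data.frame(benchmark = "principal_stress_oracle", value = edev,
                         tolerance = 1e-10, pass = edev <= 1e-10)
  if (hertz) {
    hz <- benchmark_hertz()
    rows$hertz <- data.frame(benchmark = "hertz_contact", value = hz$rel_error,
                             tolerance = 0.05, pass = hz$rel_error <= 0.05)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
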