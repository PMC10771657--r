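# Constitutive models for the knee model: isotropic linear elasticity
# (cartilage, collateral/patellar ligaments), transversely isotropic
# elasticity with a circumferential fiber frame (meniscus), and Neo-Hookean
# hyperelastic fibers (cruciate ligaments).
#
# Voigt order throughout: (11, 22, 33, 23, 13, 12) with engineering shear
# strains, so stiffness matrices map [e11,e22,e33,g23,g13,g12] to
# [s11,s22,s33,s23,s13,s12]. Units MPa.

#' Isotropic linear-elastic material
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio.
#' @return object of class `isotropic_elastic`.
#' @export
isotropic_elastic <- function(E, nu) {
  if (!(E > 0)) stop("isotropic_elastic: E must be positive")
  if (!(nu > -1 && nu < 0.5)) stop("isotropic_elastic: nu must lie in (-1, 0.5)")
  structure(list(E = E, nu = nu), class = c("isotropic_elastic", "material"))
}

#' Transversely isotropic elastic material (circumferential fiber axis)
#'
#' The distinguished (stiff) direction is the local fiber/circumferential
#' axis 1; the radial-axial plane (2-3) is the isotropy plane.
#'
#' @param E_circ circumferential (fiber) modulus, MPa.
#' @param E_plane radial = axial modulus, MPa.
#' @param nu_plane in-plane Poisson ratio (within the isotropy plane).
#' @param nu_circ_plane out-of-plane Poisson ratio (fiber-to-plane).
#' @param G_circ_plane out-of-plane shear modulus, MPa; not derivable from
#'   the moduli, configurable.
#' @return object of class `transversely_isotropic_elastic`; the in-plane
#'   shear modulus is derived as `E_plane / (2 (1 + nu_plane))`.
#' @export
transversely_isotropic_elastic <- function(E_circ = 140, E_plane = 20,
                                           nu_plane = 0.2, nu_circ_plane = 0.3,
                                           G_circ_plane = 57.7) {
  if (E_circ <= 0 || E_plane <= 0 || G_circ_plane <= 0)
    stop("transversely_isotropic_elastic: moduli must be positive")
  if (nu_circ_plane^2 >= E_circ / E_plane)
    stop("transversely_isotropic_elastic: thermodynamic restriction violated: nu_circ_plane^2 < E_circ/E_plane")
  m <- structure(list(E_circ = E_circ, E_plane = E_plane,
                      nu_plane = nu_plane, nu_circ_plane = nu_circ_plane,
                      G_circ_plane = G_circ_plane,
                      G_plane = E_plane / (2 * (1 + nu_plane))),
                 class = c("transversely_isotropic_elastic", "material"))
  # full positive-definiteness check on the compliance
  S <- .compliance_trans_iso(m)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("transversely_isotropic_elastic: compliance not positive definite; violated restriction: min eigenvalue = ",
         signif(min(ev), 4))
  m
}

#' Neo-Hookean fiber material parameters
#' @param C1 shear-like modulus, MPa.
#' @param D1 compressibility parameter, MPa^-1.
#' @return object of class `neo_hookean_params`.
#' @export
neo_hookean_params <- function(C1, D1) {
  if (!(C1 > 0)) stop("neo_hookean_params: C1 must be positive")
  if (!(D1 > 0)) stop("neo_hookean_params: D1 must be positive")
  structure(list(C1 = C1, D1 = D1), class = c("neo_hookean_params", "material"))
}

#' Default material cards for every joint region
#'
#' Articular cartilage isotropic E = 15 MPa, nu = 0.3; meniscus transversely
#' isotropic with circumferential modulus 140 MPa, radial = axial 20 MPa,
#' in-plane Poisson 0.2, out-of-plane 0.3; cruciates Neo-Hookean (ACL
#' C1 = 5.08, D1 = 0.00683; PCL C1 = 6.06, D1 = 0.0041); collateral and
#' patellar/quadriceps fibers linear with E = 60 MPa, nu = 0.3. Bone is
#' rigid and carries no card.
#'
#' @return named list of material objects keyed by region tag / material ref.
#' @export
default_materials <- function() {
  list(
    femoral_cartilage_lateral = isotropic_elastic(15, 0.3),
    femoral_cartilage_medial = isotropic_elastic(15, 0.3),
    tibial_cartilage_lateral = isotropic_elastic(15, 0.3),
    tibial_cartilage_medial = isotropic_elastic(15, 0.3),
    meniscus_lateral = transversely_isotropic_elastic(),
    meniscus_medial = transversely_isotropic_elastic(),
    acl_neo_hookean = neo_hookean_params(5.08, 0.00683),
    pcl_neo_hookean = neo_hookean_params(6.06, 0.0041),
    ligament_linear = isotropic_elastic(60, 0.3)
  )
}

#' Serialize material cards to a plain list (lossless round trip)
#' @param materials named list from [default_materials()] or equivalent.
#' @return plain nested list suitable for JSON/YAML.
#' @export
dump_materials <- function(materials) {
  lapply(materials, function(m) c(list(.class = class(m)[1L]), unclass(m)))
}

#' Rebuild material cards from a dumped list
#' @param x plain list from [dump_materials()].
#' @return named list of material objects.
#' @export
load_materials <- function(x) {
  lapply(x, function(m) {
    cls <- m$.class
    m$.class <- NULL
    switch(cls,
           isotropic_elastic = isotropic_elastic(m$E, m$nu),
           transversely_isotropic_elastic =
             transversely_isotropic_elastic(m$E_circ, m$E_plane, m$nu_plane,
                                            m$nu_circ_plane, m$G_circ_plane),
           neo_hookean_params = neo_hookean_params(m$C1, m$D1),
           stop("load_materials: unknown material class ", cls))
  })
}

#' Isotropic stiffness matrix (Voigt)
#' @param mat an `isotropic_elastic` material.
#' @return symmetric positive-definite 6x6 matrix, MPa.
#' @export
stiffness_isotropic <- function(mat) {
  E <- mat$E; nu <- mat$nu
  if (nu >= 0.5) stop("stiffness_isotropic: nu must be below 0.5")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6L, 6L)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

# compliance of the transversely isotropic model in its local frame
# (1 = circumferential, 2-3 isotropy plane)
.compliance_trans_iso <- function(mat) {
  S <- matrix(0, 6L, 6L)
  E1 <- mat$E_circ; E2 <- mat$E_plane
  n12 <- mat$nu_circ_plane; n23 <- mat$nu_plane
  S[1L, 1L] <- 1 / E1
  S[2L, 2L] <- S[3L, 3L] <- 1 / E2
  S[1L, 2L] <- S[2L, 1L] <- S[1L, 3L] <- S[3L, 1L] <- -n12 / E1
  S[2L, 3L] <- S[3L, 2L] <- -n23 / E2
  S[4L, 4L] <- 1 / mat$G_plane        # shear in the isotropy plane (23)
  S[5L, 5L] <- S[6L, 6L] <- 1 / mat$G_circ_plane  # out-of-plane (13, 12)
  S
}

#' Bond stress-transformation matrix of a rotation
#'
#' For a rotation matrix R (new = R old), returns the 6x6 matrix M with
#' sigma'_voigt = M sigma_voigt; stiffness with engineering shear strains
#' transforms as C' = M C t(M).
#'
#' @param R 3x3 rotation matrix.
#' @return 6x6 matrix.
#' @export
bond_matrix <- function(R) {
  idx <- rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(2L, 3L), c(1L, 3L), c(1L, 2L))
  M <- matrix(0, 6L, 6L)
  for (I in 1:6) for (J in 1:6) {
    i <- idx[I, 1L]; j <- idx[I, 2L]
    p <- idx[J, 1L]; q <- idx[J, 2L]
    M[I, J] <- if (p == q) R[i, p] * R[j, p]
               else R[i, p] * R[j, q] + R[i, q] * R[j, p]
  }
  M
}

#' Transversely isotropic stiffness in global axes
#'
#' Builds the local stiffness (fiber axis 1) and rotates it into global axes
#' for the given orthonormal frame.
#'
#' @param mat a `transversely_isotropic_elastic` material.
#' @param frame 3x3 matrix whose columns are the circumferential, radial and
#'   axial unit vectors in global coordinates.
#' @return symmetric positive-definite 6x6 matrix in global axes, MPa.
#' @export
stiffness_trans_iso <- function(mat, frame = diag(3)) {
  if (max(abs(crossprod(frame) - diag(3))) > 1e-8)
    stop("stiffness_trans_iso: frame is not orthonormal")
  C_local <- solve(.compliance_trans_iso(mat))
  # rotation taking local components to global: global = frame %*% local
  M <- bond_matrix(frame)
  C <- M %*% C_local %*% t(M)
  (C + t(C)) / 2
}

#' Uniaxial Neo-Hookean fiber force
#'
#' Incompressible uniaxial Neo-Hookean response: Cauchy stress
#' sigma = 2 C1 (lambda^2 - 1/lambda); the nominal (reference-area) force is
#' sigma * area / lambda. With `tension_only` (default), compressive states
#' carry no force.
#'
#' @param mat a `neo_hookean_params` material.
#' @param stretch fiber stretch lambda (> 0).
#' @param area reference cross-section area, mm^2.
#' @param tension_only drop compressive response.
#' @return axial force, N.
#' @export
neo_hookean_fiber_force <- function(mat, stretch, area, tension_only = TRUE) {
  if (any(stretch <= 0)) stop("neo_hookean_fiber_force: stretch must be positive")
  sigma <- 2 * mat$C1 * (stretch^2 - 1 / stretch)
  f <- sigma * area / stretch
  if (tension_only) f <- pmax(f, 0)
  f
}

#' Neo-Hookean strain-energy density at a material point
#'
#' Full compressible form W = C1 (I1bar - 3) + (J - 1)^2 / D1, keeping both
#' constitutive parameters available for continuum use.
#'
#' @param mat a `neo_hookean_params` material.
#' @param F deformation gradient (3x3).
#' @return energy density, MPa.
#' @export
neo_hookean_energy <- function(mat, F) {
  J <- det(F)
  if (J <= 0) stop("neo_hookean_energy: non-positive Jacobian")
  B <- F %*% t(F)
  I1bar <- sum(diag(B)) * J^(-2 / 3)
  mat$C1 * (I1bar - 3) + (J - 1)^2 / mat$D1
}

#' Per-element fiber frames for a meniscus mesh
#'
#' Circumferential direction = unit tangent of the level-set contour of the
#' distance to the outer margin, evaluated at the element centroid (computed
#' as z x grad d); axial = global z; radial completes the right-handed triad.
#' Elements with a degenerate tangent fall back to the azimuthal direction
#' about the region centroid.
#'
#' @param mesh a `tet_mesh` of a single meniscus.
#' @return list with `circumferential`, `radial`, `axial` (m x 3 matrices)
#'   and `fallback_count`.
#' @export
compute_fiber_frames <- function(mesh) {
  ctr <- (mesh$nodes[mesh$tets[, 1L], , drop = FALSE] +
          mesh$nodes[mesh$tets[, 2L], , drop = FALSE] +
          mesh$nodes[mesh$tets[, 3L], , drop = FALSE] +
          mesh$nodes[mesh$tets[, 4L], , drop = FALSE]) / 4
  m <- nrow(ctr)
  # distance to the outer margin in plan view, from the boundary surface:
  # outer-margin vertices are boundary vertices at maximal radial parameter
  grad_d <- matrix(NA_real_, m, 2L)
  if (!is.null(mesh$fields) && "rho" %in% colnames(mesh$fields)) {
    # gradient of (1 - rho) per element from nodal values and linear shape
    # functions: exact for the stored structured parameter
    for (e in seq_len(m)) {
      vid <- mesh$tets[e, ]
      X <- cbind(1, mesh$nodes[vid, 1L], mesh$nodes[vid, 2L], mesh$nodes[vid, 3L])
      coef <- tryCatch(solve(X, 1 - mesh$fields[vid, "rho"]),
                       error = function(e2) rep(NA_real_, 4L))
      grad_d[e, ] <- coef[2:3]
    }
  } else {
    # outer margin = projection boundary; distance gradient approximated
    # radially from the plan centroid
    cen <- colMeans(mesh$nodes[, 1:2, drop = FALSE])
    v <- sweep(ctr[, 1:2, drop = FALSE], 2L, cen)
    grad_d <- -v
  }
  axial <- matrix(rep(c(0, 0, 1), each = m), m, 3L)
  tang <- cbind(-grad_d[, 2L], grad_d[, 1L], 0)  # z x grad d
  nrm <- sqrt(rowSums(tang^2))
  bad <- !is.finite(nrm) | nrm < 1e-10
  nfall <- sum(bad)
  if (nfall) {
    cen <- colMeans(mesh$nodes[, 1:2, drop = FALSE])
    v <- sweep(ctr[bad, 1:2, drop = FALSE], 2L, cen)
    tang[bad, ] <- cbind(-v[, 2L], v[, 1L], 0)
    nrm[bad] <- sqrt(rowSums(tang[bad, , drop = FALSE]^2))
  }
  circ <- tang / nrm
  # right-handed triad (circ, radial, axial) with radial = axial x circ
  radial <- cbind(axial[, 2L] * circ[, 3L] - axial[, 3L] * circ[, 2L],
                  axial[, 3L] * circ[, 1L] - axial[, 1L] * circ[, 3L],
                  axial[, 1L] * circ[, 2L] - axial[, 2L] * circ[, 1L])
  list(circumferential = circ, radial = radial, axial = axial,
       fallback_count = nfall)
}
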