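# Constitutive models: closed-form stiffness values, tensor rotation against
# a brute-force oracle, Neo-Hookean fibers, fiber frames.

test_that("isotropic stiffness matches the Lame closed forms", {
  C <- stiffness_isotropic(isotropic_elastic(15, 0.3))
  expect_equal(C[1L, 1L], 15 * (1 - 0.3) / ((1 + 0.3) * (1 - 2 * 0.3)),
               tolerance = 1e-3 / C[1L, 1L])
  C0 <- stiffness_isotropic(isotropic_elastic(15, 0))
  expect_identical(C0[1L, 1L], 15)
  # hydrostatic strain maps to 3K pressure per normal component
  K <- 15 / (3 * (1 - 2 * 0.3))
  s <- as.vector(C %*% c(1, 1, 1, 0, 0, 0) * 1e-3)
  expect_equal(s[1:3], rep(3 * K * 1e-3, 3L), tolerance = 1e-10)
  expect_error(isotropic_elastic(15, 0.5), "nu")
  expect_error(isotropic_elastic(-1, 0.3), "E")
})

test_that("transversely isotropic stiffness: compliance, degeneration, positivity", {
  m <- transversely_isotropic_elastic()
  # default card: directional compliance along the fiber axis is 1/140
  S <- solve(stiffness_trans_iso(m, diag(3)))
  expect_equal(S[1L, 1L], 1 / 140, tolerance = 1e-12)
  # matched constants reproduce the isotropic tensor
  mi <- transversely_isotropic_elastic(20, 20, 0.2, 0.2, 20 / (2 * 1.2))
  expect_lt(max(abs(stiffness_trans_iso(mi, diag(3)) -
                    stiffness_isotropic(isotropic_elastic(20, 0.2)))), 1e-9)
  # symmetry and positive definiteness in arbitrary frames
  set.seed(7)
  for (i in 1:20) {
    R <- random_rotation()
    C <- stiffness_trans_iso(m, R)
    expect_lt(max(abs(C - t(C))), 1e-9 * max(abs(C)))
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  # thermodynamic restriction is enforced with a message naming it
  expect_error(transversely_isotropic_elastic(E_circ = 10, E_plane = 200,
                                              nu_circ_plane = 0.4),
               "restriction")
})

test_that("frame rotation matches the brute-force 4th-order tensor oracle", {
  m <- transversely_isotropic_elastic()
  C0 <- stiffness_trans_iso(m, diag(3))
  # voigt -> full tensor
  idx <- rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(2L, 3L), c(1L, 3L), c(1L, 2L))
  Tn <- array(0, c(3, 3, 3, 3))
  for (I in 1:6) for (J in 1:6) {
    i <- idx[I, 1L]; j <- idx[I, 2L]; p <- idx[J, 1L]; q <- idx[J, 2L]
    Tn[i, j, p, q] <- Tn[j, i, p, q] <- Tn[i, j, q, p] <- Tn[j, i, q, p] <- C0[I, J]
  }
  set.seed(11)
  for (rep in 1:3) {
    R <- random_rotation()
    Tr <- array(0, c(3, 3, 3, 3))
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
      s <- 0
      for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (d in 1:3)
        s <- s + R[i, a] * R[j, b] * R[k, cc] * R[l, d] * Tn[a, b, cc, d]
      Tr[i, j, k, l] <- s
    }
    Cr <- matrix(0, 6L, 6L)
    for (I in 1:6) for (J in 1:6)
      Cr[I, J] <- Tr[idx[I, 1L], idx[I, 2L], idx[J, 1L], idx[J, 2L]]
    expect_lt(max(abs(stiffness_trans_iso(m, R) - Cr)), 1e-9)
  }
})

test_that("frame objectivity: strain energy invariant under joint rotation", {
  m <- transversely_isotropic_elastic()
  set.seed(13)
  for (rep in 1:5) {
    R <- random_rotation()
    eps <- stats::rnorm(6L) * 0.01
    C0 <- stiffness_trans_iso(m, diag(3))
    W0 <- 0.5 * sum(eps * as.vector(C0 %*% eps))
    # rotate the strain tensor (true shear halved, then doubled back)
    E <- voigt_to_mat(c(eps[1:3], eps[4:6] / 2))
    Er <- R %*% E %*% t(R)
    eps_r <- mat_to_voigt(Er)
    eps_r[4:6] <- 2 * eps_r[4:6]
    CR <- stiffness_trans_iso(m, R)
    WR <- 0.5 * sum(eps_r * as.vector(CR %*% eps_r))
    expect_lt(abs(WR - W0) / abs(W0), 1e-8)
  }
})

test_that("Neo-Hookean fiber response: reference state, small strain, monotonicity", {
  nh <- neo_hookean_params(5.08, 0.00683)
  expect_identical(neo_hookean_fiber_force(nh, 1, 1), 0)
  # small-strain modulus 6 C1 within 0.1 %
  h <- 1e-7
  slope <- neo_hookean_fiber_force(nh, 1 + h, 1) / h
  expect_equal(slope, 6 * 5.08, tolerance = 1e-3)
  # tension-only flag
  expect_identical(neo_hookean_fiber_force(nh, 0.9, 1), 0)
  expect_lt(neo_hookean_fiber_force(nh, 0.9, 1, tension_only = FALSE), 0)
  expect_gt(neo_hookean_fiber_force(nh, 1.1, 1), 0)
  # monotone increasing on (0.5, 2) without the tension cutoff
  lam <- seq(0.5, 2, length.out = 200L)
  f <- neo_hookean_fiber_force(nh, lam, 1, tension_only = FALSE)
  expect_true(all(diff(f) > 0))
  expect_error(neo_hookean_fiber_force(nh, -0.1, 1), "stretch")
  expect_error(neo_hookean_params(-1, 0.01), "C1")
  expect_error(neo_hookean_params(5, 0), "D1")
  # continuum energy form: stress-free reference, positive away from it
  expect_equal(neo_hookean_energy(nh, diag(3)), 0)
  expect_gt(neo_hookean_energy(nh, diag(c(1.1, 1, 1))), 0)
})

test_that("fiber frames are orthonormal, azimuthal on a circular disc, and equivariant", {
  disc <- annulus_mesh(c(0, 0), c(12, 12), 0.25,
                       function(x, y) rep(0, length(x)),
                       function(x, y) rep(3, length(x)),
                       n_rho = 5L, n_theta = 72L, n_zeta = 2L)
  fr <- compute_fiber_frames(disc)
  expect_identical(fr$fallback_count, 0L)
  ctr <- (disc$nodes[disc$tets[, 1L], ] + disc$nodes[disc$tets[, 2L], ] +
          disc$nodes[disc$tets[, 3L], ] + disc$nodes[disc$tets[, 4L], ]) / 4
  az <- cbind(-ctr[, 2L], ctr[, 1L])
  az <- az / sqrt(rowSums(az^2))
  dotp <- abs(fr$circumferential[, 1L] * az[, 1L] +
              fr$circumferential[, 2L] * az[, 2L])
  expect_lt(max(acos(pmin(dotp, 1))) * 180 / pi, 2)
  # orthonormal right-handed triads
  for (e in seq(1L, nrow(ctr), by = 97L)) {
    Fm <- cbind(fr$circumferential[e, ], fr$radial[e, ], fr$axial[e, ])
    expect_lt(max(abs(crossprod(Fm) - diag(3))), 1e-10)
    expect_gt(det(Fm), 0)
  }
  # rigid rotation about z rotates the frames identically
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  disc2 <- disc
  disc2$nodes <- disc$nodes %*% t(R)
  fr2 <- compute_fiber_frames(disc2)
  expect_lt(max(abs(fr2$circumferential - fr$circumferential %*% t(R))), 1e-6)
})

test_that("material cards round-trip losslessly", {
  mats <- default_materials()
  back <- load_materials(dump_materials(mats))
  expect_identical(lapply(mats, unclass), lapply(back, unclass))
  # the default constitutive constants are housed as stated
  expect_identical(mats$acl_neo_hookean$C1, 5.08)
  expect_identical(mats$acl_neo_hookean$D1, 0.00683)
  expect_identical(mats$pcl_neo_hookean$C1, 6.06)
  expect_identical(mats$pcl_neo_hookean$D1, 0.0041)
  expect_identical(mats$meniscus_lateral$E_circ, 140)
  expect_identical(mats$meniscus_lateral$E_plane, 20)
  expect_identical(mats$femoral_cartilage_lateral$E, 15)
  expect_identical(mats$ligament_linear$E, 60)
})
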