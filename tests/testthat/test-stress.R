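# Stress postprocessing: principal values against a brute-force
# eigendecomposition oracle, Tresca/min-principal readouts, region peaks,
# percent change.

test_that("principal stresses match hand values and the eigen oracle", {
  expect_equal(principal_stresses(c(3, 1, -2, 0, 0, 0))[1L, ], c(3, 1, -2))
  expect_equal(principal_stresses(c(-5, -5, -5, 0, 0, 0))[1L, ], c(-5, -5, -5))
  set.seed(42)
  S <- matrix(stats::rnorm(6000L), ncol = 6L)
  pr <- principal_stresses(S)
  ev <- t(apply(S, 1L, function(s)
    sort(eigen(voigt_to_mat(s), symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)))
  expect_lt(max(abs(pr - ev)), 1e-10)
  # sorted descending
  expect_true(all(pr[, 1L] >= pr[, 2L] & pr[, 2L] >= pr[, 3L]))
})

test_that("Tresca stress: hydrostatic zero, uniaxial identity, pure shear 2*tau", {
  expect_equal(tresca(c(-3, -3, -3, 0, 0, 0)), 0)
  expect_equal(tresca(c(5, 0, 0, 0, 0, 0)), 5)
  tau <- 1.7
  expect_equal(tresca(c(0, 0, 0, 0, 0, tau)), 2 * tau, tolerance = 1e-12)
})

test_that("minimum principal stress and compressive magnitude", {
  mp <- min_principal(c(1, 0, -4, 0, 0, 0))
  expect_equal(mp$sigma3, -4)
  expect_equal(mp$compressive, 4)
  mp2 <- min_principal(c(2, 1, 0.5, 0, 0, 0))
  expect_equal(mp2$compressive, 0)
})

test_that("invariance under rotation and the von Mises / Tresca ordering band", {
  set.seed(5)
  S <- matrix(stats::rnorm(600L), ncol = 6L)
  tr0 <- tresca(S); mp0 <- min_principal(S)$sigma3
  for (rep in 1:3) {
    R <- random_rotation()
    Sr <- t(apply(S, 1L, function(s) {
      M <- R %*% voigt_to_mat(s) %*% t(R)
      mat_to_voigt(M)
    }))
    expect_lt(max(abs(tresca(Sr) - tr0)), 1e-9)
    expect_lt(max(abs(min_principal(Sr)$sigma3 - mp0)), 1e-9)
  }
  vm <- von_mises(S)
  expect_true(all(vm <= tr0 + 1e-12))
  expect_true(all(tr0 <= 2 / sqrt(3) * vm + 1e-12))
})

test_that("stress recovery reproduces uniform fields exactly", {
  mesh <- box_mesh(seq(0, 2, 1), seq(0, 2, 1), seq(0, 1, 0.5), region = "blk")
  mats <- list(blk = isotropic_elastic(15, 0))
  # uniform uniaxial strain along x
  eps <- 0.01
  u <- numeric(3L * nrow(mesh$nodes))
  u[seq(1L, length(u), 3L)] <- eps * mesh$nodes[, 1L]
  fld <- recover_stresses(mesh, u, mats)
  expect_lt(max(abs(fld$stress[, 1L] - 15 * eps)), 1e-10)
  expect_lt(max(abs(fld$stress[, 2:6])), 1e-10)
  # zero displacement -> zero stress
  fld0 <- recover_stresses(mesh, numeric(length(u)), mats)
  expect_identical(max(abs(fld0$stress)), 0)
})

test_that("region peaks: localization, homogeneity, determinism, empty regions", {
  # two tiny solids standing in for the lateral and medial menisci
  mk <- function(xshift, tag) {
    m <- box_mesh(c(0, 1) + xshift, c(0, 1), c(0, 1), region = tag)
    m
  }
  mesh <- merge_meshes(list(mk(5, "meniscus_lateral"), mk(-6, "meniscus_medial")))
  m <- nrow(mesh$tets)
  sig <- matrix(0, m, 6L)
  lm_el <- which(mesh$region == "meniscus_lateral")[2L]
  sig[lm_el, ] <- c(3, 0, -1, 0, 0, 0)
  ctr <- (mesh$nodes[mesh$tets[, 1L], ] + mesh$nodes[mesh$tets[, 2L], ] +
          mesh$nodes[mesh$tets[, 3L], ] + mesh$nodes[mesh$tets[, 4L], ]) / 4
  fld <- structure(list(stress = sig, region = mesh$region, centroid = ctr),
                   class = "stress_field")
  pk <- region_peaks(fld)
  expect_equal(pk$tresca[pk$region == "LM"], 4)
  expect_equal(pk$tresca[pk$region == "MM"], 0)
  expect_true(all(is.na(pk$tresca[pk$region %in% c("MFC", "LFC", "MTC", "LTC")])))
  expect_identical(pk$el_tresca[pk$region == "LM"], lm_el)
  # homogeneity: scaling the field scales every peak
  fld2 <- fld; fld2$stress <- 2 * fld$stress
  pk2 <- region_peaks(fld2)
  expect_equal(pk2$tresca[pk2$region == "LM"], 2 * pk$tresca[pk$region == "LM"])
  # determinism
  expect_identical(region_peaks(fld), pk)
})

test_that("percent change matches the reported worked examples", {
  expect_identical(percent_change(16.78, 4.175), 302)
  expect_identical(percent_change(14.88, 5.90), 152)
  expect_identical(percent_change(7, 7), 0)
  expect_equal(percent_change(16.78, 4.175, rounded = FALSE), 301.9162,
               tolerance = 1e-4)
  expect_error(percent_change(1, 0), "reference")
  expect_error(percent_change(1, -2), "reference")
})
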