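# FE core: element oracle, patch test, objectivity, contact benchmarks and
# the assembled knee model.

test_that("single TET4 stiffness matches a hand-assembled oracle", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh1 <- tet_mesh(nodes, matrix(1:4, 1L), "blk")
  K1 <- as.matrix(fe_stiffness(mesh1, list(blk = isotropic_elastic(1, 0))))
  # independent closed-form B-matrix assembly
  V <- 1 / 6
  G <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Bh <- matrix(0, 6L, 12L)
  for (a in 1:4) {
    ix <- 3L * a - 2L
    Bh[1L, ix] <- G[a, 1L]; Bh[2L, ix + 1L] <- G[a, 2L]; Bh[3L, ix + 2L] <- G[a, 3L]
    Bh[4L, ix + 1L] <- G[a, 3L]; Bh[4L, ix + 2L] <- G[a, 2L]
    Bh[5L, ix] <- G[a, 3L]; Bh[5L, ix + 2L] <- G[a, 1L]
    Bh[6L, ix] <- G[a, 2L]; Bh[6L, ix + 1L] <- G[a, 1L]
  }
  C <- stiffness_isotropic(isotropic_elastic(1, 0))
  Kh <- V * t(Bh) %*% C %*% Bh
  expect_lt(max(abs(K1 - Kh)), 1e-10)
  # nodal force from a uniaxial stretch of the free node
  u <- numeric(12L); u[10L] <- 0  # node 4 z-dof
  u[12L] <- 0.01
  expect_lt(max(abs(as.vector(K1 %*% u) - as.vector(Kh %*% u))), 1e-12)
  # duplicate assembly is bit-identical
  K2 <- as.matrix(fe_stiffness(mesh1, list(blk = isotropic_elastic(1, 0))))
  expect_identical(K1, K2)
  # zero displacement gives zero internal force
  expect_identical(as.vector(K1 %*% numeric(12L)), numeric(12L))
})

test_that("constant-strain patch test passes at 1e-8", {
  pt <- benchmark_patch_test()
  expect_lt(pt$rel_error, 1e-8)
})

test_that("assembled stiffness is objective under rigid rotation", {
  mesh <- box_mesh(seq(0, 2, 1), seq(0, 1, 0.5), seq(0, 1, 0.5))
  mats <- list(block = isotropic_elastic(15, 0.3))
  K0 <- fe_stiffness(mesh, mats)
  set.seed(3)
  R <- random_rotation()
  mesh_r <- mesh
  mesh_r$nodes <- mesh$nodes %*% t(R)
  Kr <- fe_stiffness(mesh_r, mats)
  n <- nrow(mesh$nodes)
  Rblk <- Matrix::bdiag(rep(list(R), n))
  expect_lt(max(abs(Kr - Rblk %*% K0 %*% Matrix::t(Rblk))), 1e-6 * max(abs(K0)))
})

test_that("uniaxial block compression recovers strain p/E", {
  ua <- benchmark_uniaxial()
  expect_lt(ua$rel_error, 0.01)
})

test_that("rigid sphere on elastic block matches the Hertz closed form within 5%", {
  hz <- benchmark_hertz()
  expect_lt(hz$rel_error, 0.05)
  # total contact force carries the applied load
  expect_equal(hz$total_force, 100, tolerance = 0.05)
  # contact radius in the right range
  expect_equal(hz$a_fe, hz$a_hertz, tolerance = 0.4)
})

test_that("zero load produces a zero displacement field", {
  g <- fixture("knee_geom_coarse", function()
    build_knee_geometry(knee_config(mesh = list(edge_length = 2.5, bone_facet = 2))))
  model <- fixture("knee_model", function() build_fe_model(g))
  st0 <- solve_static(model, load_case(0, increments = 1L))
  expect_identical(max(abs(st0$u_full)), 0)
})

test_that("knee solve balances the applied load and bounds penetration", {
  g <- fixture("knee_geom_coarse", function()
    build_knee_geometry(knee_config(mesh = list(edge_length = 2.5, bone_facet = 2))))
  model <- fixture("knee_model", function() build_fe_model(g))
  st <- fixture("knee_state", function() solve_static(model, load_case()))
  expect_true(st$converged)
  rep1 <- contact_report(model, st, load_case())
  expect_lt(rep1$balance_error, 0.005)
  expect_lte(rep1$max_penetration, 0.02 + 1e-9)
  # doubling the load at small deformation: the total tibial reaction doubles
  # exactly and the condyle-side pair forces double within 2%; the
  # meniscus-tibial pairs grow slightly faster than the load because rim
  # liftoff recruits contact area (a real contact-area effect, reported via
  # the pair table rather than asserted linear)
  st_a <- solve_static(model, load_case(100))
  st_b <- solve_static(model, load_case(200))
  rep_a <- contact_report(model, st_a, load_case(100))
  rep_b <- contact_report(model, st_b, load_case(200))
  expect_equal(rep_b$tibial_reaction / rep_a$tibial_reaction, 2,
               tolerance = 0.005)
  fem_pairs <- grep("meniscus-femoral", names(rep_a$pair_force), value = TRUE)
  ratio <- rep_b$pair_force[fem_pairs] / rep_a$pair_force[fem_pairs]
  expect_true(all(abs(ratio - 2) < 0.04))
})

test_that("a symmetric joint splits the load 50/50 between compartments", {
  cfg <- knee_config(medial_meniscus_inner_rim_ratio = sqrt(1 - 0.95),
                     mesh = list(edge_length = 2.5, bone_facet = 2))
  g <- build_knee_geometry(cfg)
  model <- build_fe_model(g)
  st <- solve_static(model, load_case())
  rep1 <- contact_report(model, st, load_case())
  fl <- rep1$pair_force[["lateral:meniscus-tibial"]]
  fm <- rep1$pair_force[["medial:meniscus-tibial"]]
  expect_lt(abs(fl - fm) / (fl + fm), 0.02)
})

test_that("peak meniscus Tresca is insensitive to a tenfold penalty increase", {
  g <- fixture("knee_geom_coarse", function()
    build_knee_geometry(knee_config(mesh = list(edge_length = 2.5, bone_facet = 2))))
  peak_lm <- function(pf) {
    model <- build_fe_model(g, controls = solver_controls(penalty_factor = pf))
    st <- solve_static(model, load_case())
    mesh_all <- merge_meshes(model$meshes)
    fld <- recover_stresses(mesh_all, st$u_full[seq_len(3L * nrow(mesh_all$nodes))],
                            default_materials())
    pk <- region_peaks(fld)
    pk$tresca[pk$region == "LM"]
  }
  p50 <- peak_lm(50)
  p500 <- peak_lm(500)
  expect_lt(abs(p500 - p50) / p50, 0.03)
})
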