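# Mesh primitives: volumes, watertightness, conforming level-set splits.

test_that("divergence-theorem volume matches closed forms and orientation", {
  # unit cube, 12 triangles
  cube <- box_mesh(c(0, 1), c(0, 1), c(0, 1))
  b <- boundary_surface(cube)
  expect_identical(nrow(b$triangles), 12L)
  expect_equal(compute_volume(b), 1.0, tolerance = 1e-12)
  expect_equal(sum(tet_volumes(cube$nodes, cube$tets)), 1.0, tolerance = 1e-12)

  # sphere r = 2 from a fine structured ball; radial grid graded toward the
  # equator where the profile has a vertical tangent
  rho_eq <- sin(seq(0, pi / 2, length.out = 40L))[-1L]
  ball <- annulus_mesh(c(0, 0), c(2, 2), 0,
                       function(x, y) -sqrt(pmax(4 - x^2 - y^2, 1e-8)),
                       function(x, y) sqrt(pmax(4 - x^2 - y^2, 1e-6)),
                       n_theta = 96L, n_zeta = 12L, rho_values = rho_eq)
  vs <- compute_volume(boundary_surface(ball))
  expect_equal(vs, 4 / 3 * pi * 8, tolerance = 5e-3)

  # inverted orientation flips the sign
  binv <- b
  binv$triangles <- binv$triangles[, c(1L, 3L, 2L)]
  v <- binv$vertices
  tr <- binv$triangles
  signed <- sum(v[tr[, 1L], 1L] * (v[tr[, 2L], 2L] * v[tr[, 3L], 3L] -
                                   v[tr[, 2L], 3L] * v[tr[, 3L], 2L]) -
                v[tr[, 1L], 2L] * (v[tr[, 2L], 1L] * v[tr[, 3L], 3L] -
                                   v[tr[, 2L], 3L] * v[tr[, 3L], 1L]) +
                v[tr[, 1L], 3L] * (v[tr[, 2L], 1L] * v[tr[, 3L], 2L] -
                                   v[tr[, 2L], 2L] * v[tr[, 3L], 1L])) / 6
  expect_equal(signed, -1.0, tolerance = 1e-12)

  # an open mesh is rejected
  open_surf <- surface_mesh(b$vertices, b$triangles[-1L, , drop = FALSE])
  expect_error(compute_volume(open_surf), "open mesh")
})

test_that("structured annulus and disc meshes are watertight and conforming", {
  ann <- annulus_mesh(c(1, -2), c(10, 8), 0.3,
                      function(x, y) rep(0, length(x)),
                      function(x, y) 2 + 0.02 * x,
                      n_rho = 5L, n_theta = 28L, n_zeta = 2L)
  expect_true(mesh_audit(boundary_surface(ann))$watertight)
  disc <- annulus_mesh(c(0, 0), c(5, 5), 0,
                       function(x, y) rep(0, length(x)),
                       function(x, y) rep(1, length(x)),
                       n_rho = 4L, n_theta = 20L, n_zeta = 2L)
  aud <- mesh_audit(boundary_surface(disc))
  expect_true(aud$watertight)
  expect_identical(aud$degenerate, 0L)
  expect_equal(compute_volume(boundary_surface(disc)), pi * 25,
               tolerance = 0.02)
})

test_that("level-set split conserves volume, stays watertight and matches the closed form", {
  ann <- annulus_mesh(c(0, 0), c(10, 10), 0.3,
                      function(x, y) rep(0, length(x)),
                      function(x, y) rep(2, length(x)),
                      n_rho = 5L, n_theta = 24L, n_zeta = 2L)
  vtot <- sum(tet_volumes(ann$nodes, ann$tets))
  for (iso in c(0.5, 0.71, 0.93)) {
    vb_closed <- volume_below_levelset(ann, ann$fields[, "rho"], iso)
    sp <- split_by_levelset(ann, ann$fields[, "rho"], iso)
    vols <- tet_volumes(sp$mesh$nodes, sp$mesh$tets)
    expect_equal(sum(vols), vtot, tolerance = 1e-10)
    expect_equal(sum(vols[sp$side == "below"]), vb_closed, tolerance = 1e-9)
    expect_true(mesh_audit(boundary_surface(sp$mesh))$watertight)
    # the kept half must itself be watertight
    half <- subset_mesh(sp$mesh, sp$side == "below")
    expect_true(mesh_audit(boundary_surface(half))$watertight)
  }
  # a planar cut through arbitrary geometry behaves the same way
  spy <- split_by_levelset(ann, ann$nodes[, 2L], 1.37)
  expect_equal(sum(tet_volumes(spy$mesh$nodes, spy$mesh$tets)), vtot,
               tolerance = 1e-10)
  expect_equal(sum(tet_volumes(spy$mesh$nodes, spy$mesh$tets)[spy$side == "below"]),
               volume_below_levelset(ann, ann$nodes[, 2L], 1.37),
               tolerance = 1e-9)
})

test_that("voxel-count volume agrees with the divergence theorem within 2%", {
  disc <- annulus_mesh(c(0, 0), c(6, 5), 0.3,
                       function(x, y) rep(0, length(x)),
                       function(x, y) 2 + 0.05 * x,
                       n_rho = 5L, n_theta = 32L, n_zeta = 2L)
  b <- boundary_surface(disc)
  vd <- compute_volume(b)
  vv <- voxelize_volume(b, 0.2)
  expect_lt(abs(vv - vd) / vd, 0.02)
})

test_that("tet quality measure flags degenerate elements", {
  good <- box_mesh(c(0, 1), c(0, 1), c(0, 1))
  expect_gt(mesh_quality(good)$min_quality, 0.2)
  bad <- good
  bad$nodes[, 3L] <- bad$nodes[, 3L] * 0.02   # squashed slab
  expect_lt(mesh_quality(bad)$min_quality, 0.05)
})
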