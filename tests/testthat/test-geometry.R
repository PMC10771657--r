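# Synthetic knee geometry: validation, determinism, symmetry, conformity.

test_that("configuration validation names the offending field", {
  expect_error(knee_config(cartilage_thickness = -1), "cartilage_thickness")
  expect_error(knee_config(discoid_coverage = 0.8), "discoid_coverage")
  expect_error(knee_config(discoid_coverage = 1.2), "discoid_coverage")
  expect_error(knee_config(cartilage_thickness = 30, condyle_radius_frontal = 24),
               "condyle_radius_frontal")
  expect_error(knee_config(meniscus_inner_height = 8,
                           meniscus_peripheral_height = 4),
               "meniscus_inner_height")
  expect_error(knee_config(medial_meniscus_inner_rim_ratio = 1.5),
               "medial_meniscus_inner_rim_ratio")
})

test_that("geometry construction is deterministic and watertight", {
  cfg <- knee_config()
  g1 <- build_knee_geometry(cfg)
  g2 <- build_knee_geometry(cfg)
  expect_identical(g1$solids$meniscus_lateral$mesh,
                   g2$solids$meniscus_lateral$mesh)
  expect_identical(g1$solids$femoral_cartilage_medial$mesh,
                   g2$solids$femoral_cartilage_medial$mesh)
  for (s in g1$solids) {
    expect_true(mesh_audit(s$boundary)$watertight, label = s$tag)
    expect_gt(s$volume, 0)
  }
})

test_that("mirroring the medial-lateral axis reflects the geometry exactly", {
  g <- build_knee_geometry(knee_config())
  gm <- build_knee_geometry(knee_config(lateral_sign = -1))
  for (tag in names(g$solids)) {
    a <- g$solids[[tag]]$mesh$nodes
    b <- gm$solids[[tag]]$mesh$nodes
    b[, 1L] <- -b[, 1L]
    expect_lt(max(abs(a - b)), 1e-9, label = tag)
  }
})

test_that("discoid meniscus covers the lateral plateau and conforms to cartilage", {
  cfg <- knee_config()
  g <- build_knee_geometry(cfg)
  lm <- g$solids$meniscus_lateral
  tc <- g$solids$tibial_cartilage_lateral
  # projected (plan) areas from the structured parameters: the meniscus
  # outer margin equals the plateau ellipse, the hole is the residual
  hw <- cfg$plateau_halfwidths$lateral
  area_plateau <- pi * hw[1L] * hw[2L]
  rho_in <- sqrt(1 - cfg$discoid_coverage)
  area_meniscus <- area_plateau * (1 - rho_in^2)
  expect_gte(area_meniscus / area_plateau, 0.9)
  # zero initial gap over the conforming faces, within 0.05 mm
  cl <- geometry_clearance(g)
  expect_true(all(cl$frac_top_within >= 0.95))
  expect_true(all(cl$frac_bot_within >= 0.95))
  expect_lt(max(cl$max_gap), 0.05 + 1e-9)
})

test_that("wedge profile respects the configured heights", {
  cfg <- knee_config(meniscus_peripheral_height = 4, meniscus_inner_height = 2)
  lm <- build_discoid_meniscus(cfg)
  zeta <- lm$mesh$fields[, "zeta"]
  top <- lm$mesh$nodes[zeta > 1 - 1e-9, 3L]
  thickness <- top - cfg$cartilage_thickness
  expect_gte(min(thickness), 2 - 1e-9)
  expect_lte(max(thickness), 4 + 1e-9)
})

test_that("discoid volume scales by 4x when plan dimensions double", {
  # doubling all in-plane dimensions at fixed heights; the condyle radii
  # scale with the square of the plan factor so the thickness field is
  # preserved at scaled points
  cfg1 <- knee_config()
  cfg2 <- knee_config(plateau_halfwidths = lapply(cfg1$plateau_halfwidths,
                                                  function(v) 2 * v),
                      condyle_spacing = 2 * cfg1$condyle_spacing,
                      condyle_radius_frontal = 4 * cfg1$condyle_radius_frontal,
                      condyle_radius_sagittal = 4 * cfg1$condyle_radius_sagittal)
  v1 <- build_discoid_meniscus(cfg1)$volume
  v2 <- build_discoid_meniscus(cfg2)$volume
  expect_equal(v2 / v1, 4, tolerance = 0.01)
})

test_that("medial meniscus limit cases behave", {
  # rim ratio -> 0 gives the solid-disc discoid construction on the medial side
  cfg <- knee_config(discoid_coverage = 1.0, medial_meniscus_inner_rim_ratio = 0)
  vd <- build_discoid_meniscus(cfg, side = "medial")$volume
  vm <- build_medial_meniscus(cfg)$volume
  expect_equal(vm / vd, 1, tolerance = 0.01)
  # volume strictly decreases as the rim opening grows
  v25 <- build_medial_meniscus(knee_config(medial_meniscus_inner_rim_ratio = 0.25))$volume
  v50 <- build_medial_meniscus(knee_config(medial_meniscus_inner_rim_ratio = 0.50))$volume
  expect_lt(v50, v25)
  # and the C-shaped medial meniscus is smaller than the discoid lateral
  g <- build_knee_geometry(knee_config())
  expect_lt(g$solids$meniscus_medial$volume, g$solids$meniscus_lateral$volume)
})

test_that("ligament attachments sit on the bone surfaces", {
  cfg <- knee_config()
  g <- build_knee_geometry(cfg)
  surf_dist <- function(p, surface) {
    v <- surface$vertices
    tr <- surface$triangles
    # prune by centroid distance, then exact point-to-triangle distance
    ctr <- (v[tr[, 1L], ] + v[tr[, 2L], ] + v[tr[, 3L], ]) / 3
    d2 <- (ctr[, 1L] - p[1L])^2 + (ctr[, 2L] - p[2L])^2 + (ctr[, 3L] - p[3L])^2
    best <- Inf
    for (f in order(d2)[1:30]) {
      w <- dlmfem:::closest_point_triangle(p, v[tr[f, 1L], ], v[tr[f, 2L], ],
                                           v[tr[f, 3L], ])
      proj <- w[1L] * v[tr[f, 1L], ] + w[2L] * v[tr[f, 2L], ] +
              w[3L] * v[tr[f, 3L], ]
      best <- min(best, sqrt(sum((p - proj)^2)))
    }
    best
  }
  for (lig in g$ligaments) {
    for (fb in lig$fibers) {
      expect_gt(sqrt(sum((fb["femur", ] - fb["tibia", ])^2)), 0)  # rest length
    }
    # femoral attachment within 0.5 mm of the femur surface (PQ's far end is
    # a fixed virtual point, its femoral end still lies on the femur)
    d <- surf_dist(lig$fibers[[1L]]["femur", ], g$femur_surface)
    expect_lt(d, 0.5, label = lig$name)
  }
})
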