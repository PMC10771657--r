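# Volume-ratio partitioning, anterior/posterior split, the 15-model family
# and junction smoothing.

test_that("partition hits the 15/15/15/15/40 targets and conserves volume", {
  part <- default_partition()
  fr <- part$ring_volumes / part$source_volume
  expect_equal(fr, c(0.15, 0.15, 0.15, 0.15, 0.40), tolerance = 5e-3)
  # realized fractions within 0.5 percentage points of target
  expect_true(all(abs(fr - c(0.15, 0.15, 0.15, 0.15, 0.40)) < 0.005))
  expect_equal(sum(part$ring_volumes), part$source_volume, tolerance = 1e-9)
  # anterior and posterior halves equal within 0.5 %
  expect_lt(abs(part$anterior_fraction - 0.5), 0.0025)
})

test_that("degenerate scheme [1.0] returns the input as a single region", {
  lm <- build_discoid_meniscus(knee_config())
  p1 <- partition_rings(lm, partition_scheme(1.0))
  expect_identical(length(p1$ring_volumes), 1L)
  expect_equal(p1$ring_volumes / p1$source_volume, 1, tolerance = 1e-9)
})

test_that("flat circular disc with scheme [0.5, 0.5] cuts at R/sqrt(2)", {
  # generic (metadata-free) partition path on a uniform-thickness disc:
  # equal areas split a circle at R*sqrt(0.5)
  disc <- flat_disc(radius = 12, thickness = 3)
  p <- partition_rings(disc, partition_scheme(c(0.5, 0.5)))
  expect_identical(length(p$boundaries), 1L)
  expect_equal(p$boundaries[1L], sqrt(0.5), tolerance = 0.01)
})

test_that("anterior-posterior split is an equal-volume plane and tracks translation", {
  part <- default_partition()
  # mirror-symmetric meniscus: the plane passes through the symmetry plane
  expect_lt(abs(part$split_plane - 0), 0.1)
  vols <- tet_volumes(part$mesh$nodes, part$mesh$tets)
  va <- sum(vols[part$side == "anterior"])
  vp <- sum(vols[part$side == "posterior"])
  expect_equal(va + vp, part$source_volume, tolerance = 1e-9)
  expect_lt(abs(va - vp) / (va + vp), 0.005)

  # a translated meniscus shifts the plane by the same amount (generic path)
  disc <- flat_disc(radius = 10, thickness = 2)
  p0 <- split_anterior_posterior(partition_rings(disc, partition_scheme(c(0.6, 0.4))))
  disc5 <- disc
  disc5$mesh$nodes[, 2L] <- disc5$mesh$nodes[, 2L] + 5
  disc5$boundary$vertices[, 2L] <- disc5$boundary$vertices[, 2L] + 5
  p5 <- split_anterior_posterior(partition_rings(disc5, partition_scheme(c(0.6, 0.4))))
  expect_equal(p5$split_plane - p0$split_plane, 5, tolerance = 0.1)
})

test_that("the residual family is exactly the 15 canonical models", {
  fam <- enumerate_family()
  expect_identical(length(fam), 15L)
  expected <- c("100a100p", "85a85p", "85a70p", "85a55p", "70a85p", "70a70p",
                "70a55p", "70a40p", "55a85p", "55a70p", "55a55p", "55a40p",
                "40a70p", "40a55p", "40a40p")
  expect_setequal(names(fam), expected)
  expect_false(any(c("40a85p", "85a40p") %in% names(fam)))
  for (sp in fam) {
    expect_s3_class(sp, "resection_spec")
    expect_lte(abs(sp$anterior_fraction - sp$posterior_fraction), 0.30 + 1e-9)
  }
  expect_error(resection_spec(0.85, 0.40), "0.30")
  expect_error(resection_spec(1.00, 0.85), "1.00")
  expect_error(resection_spec(0.75, 0.75), "fractions")
})

test_that("model names follow the NNaNNp convention", {
  expect_identical(model_name(resection_spec(0.85, 0.70)), "85a70p")
  expect_identical(model_name(resection_spec(1.00, 1.00)), "100a100p")
  expect_identical(model_name(resection_spec(0.40, 0.55)), "40a55p")
})

test_that("resection bookkeeping: identity, arithmetic, conservation, symmetry, nesting", {
  part <- default_partition()
  fam <- enumerate_family()
  res <- lapply(fam, function(sp) resect(part, sp))

  # identity
  expect_equal(res[["100a100p"]]$realized_residual_fraction, 1, tolerance = 1e-9)
  # equal-split arithmetic
  expect_equal(res[["85a70p"]]$realized_residual_fraction, 0.775,
               tolerance = 0.01)
  # conservation for every model
  for (m in res) {
    expect_equal(m$realized_residual_volume + m$removed_volume,
                 m$source_volume, tolerance = 1e-9 * m$source_volume)
    expect_true(mesh_audit(m$solid$boundary)$watertight, label = m$name)
  }
  # equal-split symmetry of mirrored pairs within 0.5 %
  pairs <- list(c("85a70p", "70a85p"), c("85a55p", "55a85p"),
                c("70a55p", "55a70p"), c("70a40p", "40a70p"),
                c("55a40p", "40a55p"))
  for (p in pairs) {
    v1 <- res[[p[1L]]]$realized_residual_volume
    v2 <- res[[p[2L]]]$realized_residual_volume
    expect_lt(abs(v1 - v2) / v1, 0.005, label = paste(p, collapse = "/"))
  }
  # monotone nesting: the 55a55p residual element set is contained in the
  # 70a70p residual (whole-zone removal from a shared parent partition)
  keep_set <- function(spec) {
    na <- round((1 - spec$anterior_fraction) / 0.15)
    np <- round((1 - spec$posterior_fraction) / 0.15)
    which(!((part$side == "anterior" & part$ring <= na) |
            (part$side == "posterior" & part$ring <= np)))
  }
  expect_true(all(keep_set(fam[["55a55p"]]) %in% keep_set(fam[["70a70p"]])))
  # rim-only model: positive residual width, reported
  w <- residual_rim_width(res[["40a40p"]])
  expect_gt(w, 0)
  # unreachable fractions are rejected
  expect_error(resect(part, structure(list(anterior_fraction = 0.9,
                                           posterior_fraction = 0.9),
                                      class = "resection_spec")),
               "not reachable")
})

test_that("junction smoothing bevels the step without volume drift", {
  part <- default_partition()
  fam <- enumerate_family()

  # equal-fraction model: no step, smoothing is a no-op
  m_eq <- resect(part, fam[["70a70p"]])
  expect_identical(smooth_junction(m_eq), m_eq)
  # zero band width: identity
  m <- resect(part, fam[["85a55p"]])
  expect_identical(smooth_junction(m, band_width = 0), m)

  ms <- smooth_junction(m)
  expect_true(ms$smoothing_applied)
  expect_true(mesh_audit(ms$solid$boundary)$watertight)
  # volume delta <= 1 %
  expect_lt(abs(ms$realized_residual_volume - m$realized_residual_volume) /
            m$realized_residual_volume, 0.01)
  # the dihedral discontinuity across the split plane is reduced
  expect_lt(junction_crease(ms), junction_crease(m))
})
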