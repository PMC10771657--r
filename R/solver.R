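# Small-strain TET4 finite-element solver for the tibiofemoral contact
# problem: rigid bones (tibia fixed; femur free in medial-lateral
# translation, axial translation and varus-valgus rotation), deformable
# cartilage and menisci, frictionless small-sliding node-to-surface penalty
# contact, tension-only ligament fibers with finite stretch, and a vertical
# compressive load ramp on the femur reference point.
#
# The bulk response is linear, so with a fixed contact active set the system
# is linear; the solver is an active-set Newton iteration with sparse
# Cholesky factorizations (Matrix package), deterministic by construction.

#' Solver controls
#'
#' @param n_increments load ramp steps.
#' @param tol relative residual tolerance.
#' @param max_iter maximum Newton/active-set iterations per increment.
#' @param penalty_factor penalty stiffness scale: per-area contact stiffness
#'   is `penalty_factor * E_target / h_target` (MPa/mm).
#' @param max_penetration allowed residual penetration, mm; exceeding it
#'   triggers automatic penalty escalation (x10, up to 3 times).
#' @param regularization weak grounding stiffness (N/mm) on the free femur
#'   degrees of freedom, removing the neutral rigid-body mode before contact
#'   engages; far below any physical stiffness in the model.
#' @return list of controls.
#' @export
solver_controls <- function(n_increments = 1L, tol = 1e-6, max_iter = 50L,
                            penalty_factor = 50, max_penetration = 0.02,
                            regularization = 1e-3) {
  list(n_increments = as.integer(n_increments), tol = tol,
       max_iter = as.integer(max_iter), penalty_factor = penalty_factor,
       max_penetration = max_penetration, regularization = regularization)
}

#' Load case: vertical compression on the femur
#' @param axial_force compressive force, N (applied along -z).
#' @param increments ramp steps (mirrors `solver_controls`).
#' @param tolerance relative residual tolerance.
#' @return list of class `load_case`.
#' @export
load_case <- function(axial_force = 1150, increments = 1L, tolerance = 1e-6) {
  stopifnot(axial_force >= 0, increments >= 1L)
  structure(list(axial_force = axial_force, increments = as.integer(increments),
                 tolerance = tolerance), class = "load_case")
}

# --------------------------------------------------------------------------
# Element machinery

# shape-function gradients and volumes for all elements:
# returns list(grad = m x 4 x 3 array, vol = m vector)
element_gradients <- function(mesh) {
  nodes <- mesh$nodes; tets <- mesh$tets
  m <- nrow(tets)
  p1 <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3L], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4L], , drop = FALSE] - p1
  # inverse of M = rbind(e1, e2, e3) per element via adjugate
  det <- e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
         e1[, 2L] * (e2[, 1L] * e3[, 3L] - e2[, 3L] * e3[, 1L]) +
         e1[, 3L] * (e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L])
  vol <- det / 6
  # rows of inv(M) give gradients of barycentric coords 2..4 w.r.t. x:
  # inv(M)[j, i] = cof(M)[i, j] / det
  cof <- function(a, b) {
    # cofactor matrix entries of M = [e1; e2; e3]
    cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
          a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
          a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  }
  # grad(L_{k+1}) = (e_i x e_j)/det with (i,j) cyclic complement of k
  g2 <- cof(e2, e3) / det
  g3 <- cof(e3, e1) / det
  g4 <- cof(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  grad <- array(0, c(m, 4L, 3L))
  grad[, 1L, ] <- g1; grad[, 2L, ] <- g2; grad[, 3L, ] <- g3; grad[, 4L, ] <- g4
  list(grad = grad, vol = vol)
}

# per-element 6x6 stiffness array (m x 6 x 6) for a region's material
element_C <- function(mesh, materials) {
  m <- nrow(mesh$tets)
  Call <- array(0, c(m, 6L, 6L))
  for (tag in unique(mesh$region)) {
    idx <- which(mesh$region == tag)
    mat <- materials[[tag]]
    if (is.null(mat))
      stop("assemble: no material card for region '", tag, "'")
    if (inherits(mat, "isotropic_elastic")) {
      C <- stiffness_isotropic(mat)
      for (e in idx) Call[e, , ] <- C
    } else if (inherits(mat, "transversely_isotropic_elastic")) {
      sub <- subset_mesh(mesh, mesh$region == tag)
      fr <- compute_fiber_frames(sub)
      for (k in seq_along(idx)) {
        Fm <- cbind(fr$circumferential[k, ], fr$radial[k, ], fr$axial[k, ])
        Call[idx[k], , ] <- stiffness_trans_iso(mat, Fm)
      }
    } else {
      stop("assemble: unsupported bulk material for region '", tag, "'")
    }
  }
  Call
}

# B operator entries per element: strain voigt = B %*% u_e (12 dofs)
# returned as m x 6 x 12 array
element_B <- function(grad) {
  m <- dim(grad)[1L]
  B <- array(0, c(m, 6L, 12L))
  for (a in 1:4) {
    ix <- 3L * (a - 1L) + 1L; iy <- ix + 1L; iz <- ix + 2L
    gx <- grad[, a, 1L]; gy <- grad[, a, 2L]; gz <- grad[, a, 3L]
    B[, 1L, ix] <- gx
    B[, 2L, iy] <- gy
    B[, 3L, iz] <- gz
    B[, 4L, iy] <- gz; B[, 4L, iz] <- gy
    B[, 5L, ix] <- gz; B[, 5L, iz] <- gx
    B[, 6L, ix] <- gy; B[, 6L, iy] <- gx
  }
  B
}

#' Assemble the global stiffness of a tet mesh
#'
#' Linear-elastic TET4 stiffness, symmetric; meniscus regions use per-element
#' transversely isotropic stiffness in their fiber frames. Deterministic
#' assembly ordering: repeated calls are bit-identical.
#'
#' @param mesh a `tet_mesh`.
#' @param materials named material cards keyed by region tag.
#' @return sparse symmetric matrix (3n x 3n), N/mm.
#' @export
fe_stiffness <- function(mesh, materials) {
  eg <- element_gradients(mesh)
  if (any(eg$vol <= 0)) stop("fe_stiffness: non-positive element volume")
  B <- element_B(eg$grad)
  Call <- element_C(mesh, materials)
  m <- nrow(mesh$tets)
  Ke <- array(0, c(m, 12L, 12L))
  for (p in 1:6) for (q in 1:6) {
    cpq <- Call[, p, q]
    if (all(cpq == 0)) next
    Bp <- matrix(B[, p, ], nrow = m); Bq <- matrix(B[, q, ], nrow = m)
    # Ke[m, i, j] += vol * cpq * Bp[, i] * Bq[, j]
    w <- eg$vol * cpq
    for (i in 1:12) {
      bi <- Bp[, i]
      if (!any(bi != 0)) next
      Ke[, i, ] <- matrix(Ke[, i, ], nrow = m) + (w * bi) * Bq
    }
  }
  dof <- t(apply(mesh$tets, 1L, function(v) as.vector(rbind(3L * v - 2L, 3L * v - 1L, 3L * v))))
  ii <- array(0L, c(m, 12L, 12L)); jj <- array(0L, c(m, 12L, 12L))
  for (i in 1:12) for (j in 1:12) { ii[, i, j] <- dof[, i]; jj[, i, j] <- dof[, j] }
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(Ke), dims = c(3L, 3L) * nrow(mesh$nodes),
                            symmetric = FALSE)
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Recover element strains from nodal displacements
#' @param mesh a `tet_mesh`.
#' @param u displacement vector (3n).
#' @return m x 6 matrix of Voigt strains (engineering shears).
#' @export
element_strains <- function(mesh, u) {
  eg <- element_gradients(mesh)
  B <- element_B(eg$grad)
  dof <- t(apply(mesh$tets, 1L, function(v) as.vector(rbind(3L * v - 2L, 3L * v - 1L, 3L * v))))
  ue <- matrix(u[dof], nrow = nrow(dof))
  m <- nrow(dof)
  eps <- matrix(0, m, 6L)
  for (p in 1:6) eps[, p] <- rowSums(matrix(B[, p, ], nrow = m) * ue)
  eps
}

#' Mesh the deformable solids of a knee geometry
#'
#' Returns the merged tetrahedral mesh of the six deformable solids
#' (cartilage layers and menisci), optionally regenerated at a different
#' target edge length. Bones remain rigid surfaces and are not
#' volume-meshed. Every element carries its region tag.
#'
#' @param geometry a `knee_geometry`.
#' @param edge_length optional target element edge length (mm) for cartilage
#'   and menisci; NULL keeps the geometry's own meshes.
#' @return a `tet_mesh` with region tags and structured nodal fields.
#' @export
mesh_solids <- function(geometry, edge_length = NULL) {
  if (!is.null(edge_length)) {
    cfg <- geometry$config
    cfg$mesh$edge_length <- edge_length
    geometry <- build_knee_geometry(cfg)
  }
  mesh <- merge_meshes(lapply(geometry$solids, `[[`, "mesh"))
  q <- mesh_quality(mesh)
  if (q$min_quality < 0.05)
    warning(sprintf("mesh_solids: %d element(s) below the quality floor (min %.3f)",
                    q$n_below, q$min_quality))
  mesh
}

#' Tet element quality (scaled shape measure)
#'
#' Per-element quality 6 sqrt(2) V / l_max^3 (1 for the regular tetrahedron,
#' 0 for degenerate slivers).
#'
#' @param mesh a `tet_mesh`.
#' @param floor quality floor used for the count.
#' @return list: min_quality, n_below, quality vector.
#' @export
mesh_quality <- function(mesh, floor = 0.05) {
  v <- tet_volumes(mesh$nodes, mesh$tets)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
  lmax2 <- 0
  for (p in pairs) {
    d <- mesh$nodes[mesh$tets[, p[1L]], , drop = FALSE] -
         mesh$nodes[mesh$tets[, p[2L]], , drop = FALSE]
    lmax2 <- pmax(lmax2, rowSums(d^2))
  }
  q <- 6 * sqrt(2) * v / lmax2^1.5
  list(min_quality = min(q), n_below = sum(q < floor), quality = q)
}

# --------------------------------------------------------------------------
# Surfaces, tributary areas, contact pairing

# boundary facets of a solid filtered by mean zeta (structured surfaces)
surface_facets <- function(mesh, zeta_range) {
  faces <- tet_faces(mesh$tets)
  key <- face_key(faces)
  cnt <- table(key)
  bf <- faces[cnt[key] == 1L, , drop = FALSE]
  z <- (mesh$fields[bf[, 1L], "zeta"] + mesh$fields[bf[, 2L], "zeta"] +
        mesh$fields[bf[, 3L], "zeta"]) / 3
  bf[z >= zeta_range[1L] & z <= zeta_range[2L], , drop = FALSE]
}

# nodal tributary areas on a facet set
tributary_areas <- function(nodes, facets) {
  s <- surface_mesh(nodes, facets)
  ar <- triangle_areas(s)
  trib <- numeric(nrow(nodes))
  for (k in 1:3) {
    t <- tapply(ar / 3, facets[, k], sum)
    trib[as.integer(names(t))] <- trib[as.integer(names(t))] + t
  }
  trib
}

# closest point on triangle (p1,p2,p3) to x; returns barycentric weights
closest_point_triangle <- function(x, p1, p2, p3) {
  e1 <- p2 - p1; e2 <- p3 - p1; d <- x - p1
  a <- sum(e1 * e1); b <- sum(e1 * e2); c <- sum(e2 * e2)
  d1 <- sum(e1 * d); d2 <- sum(e2 * d)
  det <- a * c - b * b
  s <- (c * d1 - b * d2) / det
  t <- (a * d2 - b * d1) / det
  # clamp into the triangle
  if (s < 0) s <- 0
  if (t < 0) t <- 0
  if (s + t > 1) { f <- s + t; s <- s / f; t <- t / f }
  c(1 - s - t, s, t)
}

#' Create a small-sliding node-to-surface contact pair
#'
#' Pairs every follower node with its nearest target facet at initialization
#' (pairing and normals then stay fixed), with penalty stiffness
#' `penalty_factor * E_target / h_target` times the follower tributary area.
#'
#' @param follower_mesh,follower_nodes follower solid and node ids into it.
#' @param follower_offset global dof offset of the follower solid (nodes).
#' @param target_mesh,target_facets target solid and facet matrix into it.
#' @param target_offset global node offset of the target solid.
#' @param E_target,h_target target modulus (MPa) and element size (mm).
#' @param penalty_factor dimensionless penalty scale.
#' @param follower_areas tributary areas of the follower nodes, mm^2.
#' @param max_gap followers farther than this at start are not paired.
#' @return list of constraint records (class `contact_pair`).
#' @export
contact_pair <- function(follower_mesh, follower_nodes, follower_offset,
                         target_mesh, target_facets, target_offset,
                         E_target, h_target, penalty_factor,
                         follower_areas, max_gap = 3) {
  if (!nrow(target_facets) || !length(follower_nodes))
    return(structure(list(constraints = list(), label = ""), class = "contact_pair"))
  tn <- triangle_normals(surface_mesh(target_mesh$nodes, target_facets))
  tc <- (target_mesh$nodes[target_facets[, 1L], , drop = FALSE] +
         target_mesh$nodes[target_facets[, 2L], , drop = FALSE] +
         target_mesh$nodes[target_facets[, 3L], , drop = FALSE]) / 3
  k_area <- penalty_factor * E_target / h_target
  constraints <- vector("list", length(follower_nodes))
  nc <- 0L
  for (fi in seq_along(follower_nodes)) {
    nf <- follower_nodes[fi]
    x <- follower_mesh$nodes[nf, ]
    d2 <- (tc[, 1L] - x[1L])^2 + (tc[, 2L] - x[2L])^2 + (tc[, 3L] - x[3L])^2
    cand <- order(d2)[seq_len(min(12L, nrow(target_facets)))]
    best <- NULL; best_d <- Inf
    for (f in cand) {
      w <- closest_point_triangle(x, target_mesh$nodes[target_facets[f, 1L], ],
                                  target_mesh$nodes[target_facets[f, 2L], ],
                                  target_mesh$nodes[target_facets[f, 3L], ])
      proj <- w[1L] * target_mesh$nodes[target_facets[f, 1L], ] +
              w[2L] * target_mesh$nodes[target_facets[f, 2L], ] +
              w[3L] * target_mesh$nodes[target_facets[f, 3L], ]
      dd <- sqrt(sum((x - proj)^2))
      if (dd < best_d) { best_d <- dd; best <- list(f = f, w = w, proj = proj) }
    }
    if (best_d > max_gap) next
    f <- best$f
    n <- tn[f, ]
    # chordal faceting of curved targets can report spurious sub-element
    # initial penetration; conforming interfaces are adjusted to exact
    # initial touch (zero load then produces zero contact force)
    g0 <- max(0, sum(n * (x - best$proj)))
    # dof indices (global, unreduced): follower node + 3 target vertices
    fdof <- 3L * (follower_offset + nf - 1L) + 1:3
    tverts <- target_facets[f, ] + target_offset
    tdof <- as.vector(vapply(tverts, function(v) 3L * (v - 1L) + 1:3, integer(3L)))
    dofs <- c(fdof, tdof)
    coef <- c(n, -best$w[1L] * n, -best$w[2L] * n, -best$w[3L] * n)
    nc <- nc + 1L
    constraints[[nc]] <- list(dofs = dofs, coef = coef, g0 = g0,
                              k = k_area * follower_areas[nf],
                              area = follower_areas[nf])
  }
  structure(list(constraints = constraints[seq_len(nc)]), class = "contact_pair")
}

# --------------------------------------------------------------------------
# FE model container and static solve

#' Assemble a finite-element joint model
#'
#' Merges the deformable solids (with a possibly resected lateral meniscus),
#' assembles per-solid stiffness blocks, boundary conditions (tibial
#' cartilage base fixed, femoral cartilage bone-side tied to the femur rigid
#' body, meniscus peripheral-rim roots fixed), contact pairs and ligament
#' fibers.
#'
#' @param geometry a `knee_geometry`.
#' @param materials material cards; default [default_materials()].
#' @param lateral_meniscus optional replacement `solid_region` for the
#'   lateral meniscus (a resection model's residual solid).
#' @param controls solver controls.
#' @param stiffness_cache optional environment reusing per-solid stiffness
#'   blocks across models (only unchanged solids are reused).
#' @return object of class `fe_model`.
#' @export
build_fe_model <- function(geometry, materials = default_materials(),
                           lateral_meniscus = NULL,
                           controls = solver_controls(),
                           stiffness_cache = NULL) {
  solids <- geometry$solids
  if (!is.null(lateral_meniscus)) solids$meniscus_lateral <- lateral_meniscus
  tags <- names(solids)
  meshes <- lapply(solids, `[[`, "mesh")
  nn <- vapply(meshes, function(m) nrow(m$nodes), 0L)
  offset <- cumsum(c(0L, nn))[seq_along(nn)]
  names(offset) <- tags
  ntot <- sum(nn)

  Kblocks <- vector("list", length(tags)); names(Kblocks) <- tags
  for (tg in tags) {
    msh <- meshes[[tg]]
    cache_key <- paste(tg, nrow(msh$tets), nrow(msh$nodes),
                       format(sum(msh$nodes), digits = 15), sep = "_")
    if (!is.null(stiffness_cache) && !is.null(stiffness_cache[[cache_key]])) {
      Kblocks[[tg]] <- stiffness_cache[[cache_key]]
    } else {
      Kblocks[[tg]] <- fe_stiffness(meshes[[tg]], materials)
      if (!is.null(stiffness_cache)) stiffness_cache[[cache_key]] <- Kblocks[[tg]]
    }
  }
  Kbulk <- Matrix::bdiag(Kblocks)
  # pad for the 3 femur rigid dofs
  Kbulk <- Matrix::bdiag(Kbulk, Matrix::Matrix(0, 3L, 3L, sparse = TRUE))
  ndof <- 3L * ntot + 3L
  qdof <- 3L * ntot + 1:3   # (tx, tz, ry)

  cfg <- geometry$config
  zr <- cfg$cartilage_thickness + cfg$meniscus_inner_height +
        cfg$cartilage_thickness + 10   # femur reference height
  ref <- c(0, cfg$condyle_ap_offset, zr)

  fixed_nodes <- integer(0)
  tied <- NULL   # data.frame node (global), x, z coords for the rigid map
  for (tg in tags) {
    msh <- meshes[[tg]]
    zeta <- msh$fields[, "zeta"]
    if (grepl("^tibial_cartilage", tg)) {
      fixed_nodes <- c(fixed_nodes, offset[tg] + which(zeta < 1e-9))
    } else if (grepl("^femoral_cartilage", tg)) {
      tn <- which(zeta > 1 - 1e-9)
      tied <- rbind(tied, cbind(node = offset[tg] + tn,
                                x = msh$nodes[tn, 1L], z = msh$nodes[tn, 3L]))
    } else if (grepl("^meniscus", tg)) {
      rho <- msh$fields[, "rho"]
      roots <- which(rho > max(rho) - 1e-9 & zeta < 1e-9)
      fixed_nodes <- c(fixed_nodes, offset[tg] + roots)
    }
  }

  # reduction map T: unreduced dofs -> [free nodal dofs, q]
  fixed_nodes <- as.integer(fixed_nodes)
  tied_nodes_i <- as.integer(tied[, "node"])
  fixed_dofs <- as.vector(vapply(fixed_nodes, function(v) 3L * (v - 1L) + 1:3,
                                 integer(3L)))
  tied_dofs <- as.vector(vapply(tied_nodes_i, function(v) 3L * (v - 1L) + 1:3,
                                integer(3L)))
  is_free <- rep(TRUE, ndof)
  is_free[fixed_dofs] <- FALSE
  is_free[tied_dofs] <- FALSE
  is_free[qdof] <- FALSE
  free_dofs <- which(is_free)
  nred <- length(free_dofs) + 3L
  # triplets for T (ndof x nred): free dofs identity, tied -> q, q identity
  ti <- c(free_dofs, qdof)
  tj <- c(seq_along(free_dofs), nred - 2L, nred - 1L, nred)
  tx <- rep(1, length(ti))
  # tied node u = (tx + ry (z - zr), 0, tz - ry (x - xr))
  tn_nodes <- tied_nodes_i
  ti <- c(ti, 3L * (tn_nodes - 1L) + 1L, 3L * (tn_nodes - 1L) + 1L,
              3L * (tn_nodes - 1L) + 3L, 3L * (tn_nodes - 1L) + 3L)
  tj <- c(tj, rep(nred - 2L, length(tn_nodes)), rep(nred, length(tn_nodes)),
              rep(nred - 1L, length(tn_nodes)), rep(nred, length(tn_nodes)))
  tx <- c(tx, rep(1, length(tn_nodes)), tied[, "z"] - ref[3L],
              rep(1, length(tn_nodes)), -(tied[, "x"] - ref[1L]))
  Tmat <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, nred))

  # contact pairs
  h <- cfg$mesh$edge_length
  pairs <- list()
  add_pair <- function(label, fol_tag, fol_zeta, tar_tag, tar_zeta) {
    fmesh <- meshes[[fol_tag]]
    fz <- fmesh$fields[, "zeta"]
    fnodes <- which(fz >= fol_zeta[1L] & fz <= fol_zeta[2L])
    ffacets <- surface_facets(fmesh, fol_zeta)
    areas <- tributary_areas(fmesh$nodes, ffacets)
    tmesh <- meshes[[tar_tag]]
    tfacets <- surface_facets(tmesh, tar_zeta)
    cp <- contact_pair(fmesh, fnodes, offset[fol_tag], tmesh, tfacets,
                       offset[tar_tag], E_target = 15, h_target = h,
                       penalty_factor = controls$penalty_factor,
                       follower_areas = areas)
    cp$label <- label
    pairs[[label]] <<- cp
  }
  for (side in c("lateral", "medial")) {
    men <- paste0("meniscus_", side)
    fc <- paste0("femoral_cartilage_", side)
    tc <- paste0("tibial_cartilage_", side)
    add_pair(paste0(side, ":meniscus-femoral"), men, c(1 - 1e-9, 1), fc, c(0, 1e-9))
    add_pair(paste0(side, ":meniscus-tibial"), men, c(0, 1e-9), tc, c(1 - 1e-9, 1))
    add_pair(paste0(side, ":cartilage-cartilage"), fc, c(0, 1e-9), tc, c(1 - 1e-9, 1))
  }

  # ligament fibers: femoral end moves with q, other end fixed
  fibers <- list()
  for (lig in geometry$ligaments) {
    mat <- materials[[lig$material_ref]]
    for (fi in seq_along(lig$fibers)) {
      fb <- lig$fibers[[fi]]
      fibers[[length(fibers) + 1L]] <-
        list(name = lig$name, femur = fb["femur", ], fixed = fb["tibia", ],
             area = lig$cross_section_area, L0 = lig$rest_lengths[fi],
             material = mat)
    }
  }

  structure(list(geometry = geometry, materials = materials,
                 meshes = meshes, tags = tags, offset = offset,
                 Kbulk = Kbulk, Tmat = Tmat, ndof = ndof, nred = nred,
                 qdof = qdof, free_dofs = free_dofs,
                 fixed_nodes = fixed_nodes, tied_nodes = tn_nodes,
                 ref = ref, pairs = pairs, fibers = fibers,
                 controls = controls),
            class = "fe_model")
}

# fiber force and (numeric) tangent on the rigid dofs q = (tx, tz, ry)
# small rotations: femoral attachment displacement = A(X) q
.fiber_generalized <- function(model, q) {
  f <- numeric(3L)
  for (fb in model$fibers) {
    X <- fb$femur
    A <- rbind(c(1, 0, X[3L] - model$ref[3L]),
               c(0, 0, 0),
               c(0, 1, -(X[1L] - model$ref[1L])))
    xf <- X + as.vector(A %*% q)
    d <- xf - fb$fixed
    L <- sqrt(sum(d^2))
    lambda <- L / fb$L0
    Fn <- if (inherits(fb$material, "neo_hookean_params")) {
      neo_hookean_fiber_force(fb$material, lambda, fb$area)
    } else {
      # linear fiber, tension-only
      max(0, fb$material$E * (lambda - 1)) * fb$area
    }
    # force on the femur attachment points along -d (fiber pulls ends together)
    Ff <- -Fn * d / L
    f <- f + as.vector(t(A) %*% Ff)
  }
  f
}

.fiber_tangent <- function(model, q, h = 1e-6) {
  Kq <- matrix(0, 3L, 3L)
  f0 <- .fiber_generalized(model, q)
  for (k in 1:3) {
    qk <- q; qk[k] <- qk[k] + h
    Kq[, k] <- -(.fiber_generalized(model, qk) - f0) / h
  }
  (Kq + t(Kq)) / 2
}

#' Solve the static contact problem
#'
#' Incremental load ramp with active-set Newton iterations: with a fixed
#' contact active set the bulk problem is linear, so each iteration solves a
#' sparse SPD system exactly; convergence requires a stable active set and a
#' relative residual below tolerance. Penalty is escalated (x10, up to 3
#' times) if residual penetration exceeds the allowance.
#'
#' @param model an `fe_model`.
#' @param load a `load_case`.
#' @return object of class `solution_state`: reduced and full displacements,
#'   femur rigid dofs, contact state, convergence log.
#' @export
solve_static <- function(model, load = load_case()) {
  ctl <- model$controls
  nred <- model$nred
  cons <- do.call(c, lapply(model$pairs, `[[`, "constraints"))
  ncon <- length(cons)
  # constraint matrices in unreduced dofs: D (ncon x ndof), g0, k
  if (ncon) {
    ci <- unlist(lapply(seq_len(ncon), function(c) rep(c, length(cons[[c]]$dofs))))
    cj <- unlist(lapply(cons, `[[`, "dofs"))
    cx <- unlist(lapply(cons, `[[`, "coef"))
    D <- Matrix::sparseMatrix(i = ci, j = cj, x = cx,
                              dims = c(ncon, model$ndof))
    Dr <- D %*% model$Tmat                  # reduced constraint operator
    g0 <- vapply(cons, `[[`, 0, "g0")
    kvec <- vapply(cons, `[[`, 0, "k")
  } else {
    Dr <- NULL; g0 <- numeric(0); kvec <- numeric(0)
  }
  Kred0 <- Matrix::forceSymmetric(Matrix::t(model$Tmat) %*% model$Kbulk %*% model$Tmat)
  # weak grounding of the rigid dofs
  reg_idx <- (nred - 2L):nred
  reg <- Matrix::sparseMatrix(i = reg_idx, j = reg_idx,
                              x = rep(ctl$regularization, 3L),
                              dims = c(nred, nred))
  Fext <- numeric(nred)
  Fext[nred - 1L] <- -load$axial_force      # tz dof carries the axial load

  u <- numeric(nred)
  esc <- 0L
  log <- list()
  active_prev <- rep(FALSE, ncon)
  converged_all <- TRUE
  for (inc in seq_len(load$increments)) {
    lam <- inc / load$increments
    it <- 0L
    repeat {
      it <- it + 1L
      gaps <- if (ncon) g0 + as.vector(Dr %*% u) else numeric(0)
      active <- gaps <= 0
      q <- u[reg_idx]
      ffib <- .fiber_generalized(model, q)
      Kfib <- .fiber_tangent(model, q)
      K <- Kred0 + reg
      if (any(active)) {
        Da <- Dr[active, , drop = FALSE]
        K <- K + Matrix::forceSymmetric(Matrix::t(Da) %*% (kvec[active] * Da))
      }
      K <- K + Matrix::forceSymmetric(Matrix::sparseMatrix(
        i = rep(reg_idx, 3L), j = rep(reg_idx, each = 3L),
        x = as.vector(Kfib), dims = c(nred, nred)))
      r <- lam * Fext - as.vector(Kred0 %*% u) - ctl$regularization * u *
           (seq_len(nred) %in% reg_idx)
      if (any(active))
        r <- r - as.vector(Matrix::t(Dr[active, , drop = FALSE]) %*%
                           (kvec[active] * gaps[active]))
      r[reg_idx] <- r[reg_idx] + ffib
      rnorm <- sqrt(sum(r^2)) / max(1, lam * load$axial_force)
      if (rnorm < load$tolerance && identical(active, active_prev) && it > 1L)
        break
      du <- tryCatch({
        ch <- Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = FALSE,
                               perm = TRUE)
        as.vector(Matrix::solve(ch, r, system = "A"))
      }, error = function(e) stop("solve_static: linear solve failed: ",
                                  conditionMessage(e)))
      u <- u + du
      active_prev <- active
      if (it >= ctl$max_iter) {
        converged_all <- FALSE
        warning(sprintf("solve_static: increment %d not converged (residual %.2e)",
                        inc, rnorm))
        break
      }
    }
    log[[inc]] <- list(increment = inc, iterations = it, residual = rnorm,
                       n_active = sum(active))
    # penetration audit at full load
    if (inc == load$increments && ncon) {
      pen <- -pmin(0, g0 + as.vector(Dr %*% u))
      while (max(pen) > ctl$max_penetration && esc < 3L) {
        esc <- esc + 1L
        kvec <- kvec * 10
        # re-solve the final state with the stiffer penalty
        it2 <- 0L
        repeat {
          it2 <- it2 + 1L
          gaps <- g0 + as.vector(Dr %*% u)
          active <- gaps <= 0
          q <- u[reg_idx]
          ffib <- .fiber_generalized(model, q)
          Kfib <- .fiber_tangent(model, q)
          K <- Kred0 + reg
          if (any(active)) {
            Da <- Dr[active, , drop = FALSE]
            K <- K + Matrix::forceSymmetric(Matrix::t(Da) %*% (kvec[active] * Da))
          }
          K <- K + Matrix::forceSymmetric(Matrix::sparseMatrix(
        i = rep(reg_idx, 3L), j = rep(reg_idx, each = 3L),
        x = as.vector(Kfib), dims = c(nred, nred)))
          r <- Fext - as.vector(Kred0 %*% u) - ctl$regularization * u *
               (seq_len(nred) %in% reg_idx)
          if (any(active))
            r <- r - as.vector(Matrix::t(Dr[active, , drop = FALSE]) %*%
                               (kvec[active] * gaps[active]))
          r[reg_idx] <- r[reg_idx] + ffib
          rnorm <- sqrt(sum(r^2)) / max(1, load$axial_force)
          if ((rnorm < load$tolerance && identical(active, active_prev) && it2 > 1L) ||
              it2 >= ctl$max_iter) break
          ch <- Matrix::Cholesky(Matrix::forceSymmetric(K), LDL = FALSE,
                                 perm = TRUE)
          u <- u + as.vector(Matrix::solve(ch, r, system = "A"))
          active_prev <- active
        }
        pen <- -pmin(0, g0 + as.vector(Dr %*% u))
        log[[length(log) + 1L]] <- list(increment = paste0("escalation", esc),
                                        iterations = it2, residual = rnorm,
                                        max_penetration = max(pen))
      }
    }
  }
  ufull <- as.vector(model$Tmat %*% u)
  gaps <- if (ncon) g0 + as.vector(Dr %*% u) else numeric(0)
  forces <- if (ncon) kvec * pmax(0, -gaps) else numeric(0)
  # reaction forces at constrained (fixed) dofs from the bulk + contact state
  fint <- as.vector(model$Kbulk %*% ufull)
  if (ncon && any(gaps < 0)) {
    act <- gaps < 0
    fint <- fint + as.vector(Matrix::t(D[act, , drop = FALSE]) %*%
                             (kvec[act] * gaps[act]))
  }
  structure(list(u = u, u_full = ufull, q = u[reg_idx],
                 gaps = gaps, contact_forces = forces,
                 constraint_sets = lapply(model$pairs, function(p)
                   length(p$constraints)),
                 penalty_escalations = esc,
                 internal_forces = fint,
                 converged = converged_all,
                 log = log),
            class = "solution_state")
}

#' @export
print.solution_state <- function(x, ...) {
  cat(sprintf("solution_state: %s, femur dofs (tx, tz, ry) = (%.4f mm, %.4f mm, %.5f rad)\n",
              if (x$converged) "converged" else "NOT CONVERGED",
              x$q[1L], x$q[2L], x$q[3L]))
  invisible(x)
}

#' Contact and equilibrium report for a converged solution
#'
#' @param model the `fe_model`.
#' @param state the `solution_state`.
#' @param load the `load_case` that produced it.
#' @return list: per-pair normal force, active area and anterior force share,
#'   maximum penetration, total tibial-side reaction and its relative
#'   balance error.
#' @export
contact_report <- function(model, state, load = load_case()) {
  cons <- do.call(c, lapply(model$pairs, `[[`, "constraints"))
  npair <- vapply(model$pairs, function(p) length(p$constraints), 0L)
  pair_id <- rep(names(model$pairs), npair)
  act <- state$gaps < 0
  pair_force <- tapply(state$contact_forces, pair_id, sum)[names(model$pairs)]
  # anterior (y > 0) share of each pair's follower-node contact force
  all_y <- unlist(lapply(model$tags, function(tg) model$meshes[[tg]]$nodes[, 2L]))
  fol_y <- vapply(cons, function(cc) all_y[(cc$dofs[1L] - 1L) %/% 3L + 1L], 0)
  pair_anterior_share <- vapply(names(model$pairs), function(lb) {
    idx <- pair_id == lb
    tot <- sum(state$contact_forces[idx])
    if (tot <= 0) return(NA_real_)
    sum(state$contact_forces[idx & fol_y > 0]) / tot
  }, 0)
  pair_area <- vapply(names(model$pairs), function(lb) {
    idx <- which(pair_id == lb)
    sum(vapply(cons[idx[act[idx]]], `[[`, 0, "area"))
  }, 0)
  # tibial-side reaction: z components at fixed dofs
  fixed_dofs_z <- 3L * (model$fixed_nodes - 1L) + 3L
  rz <- sum(state$internal_forces[fixed_dofs_z])
  balance_err <- abs(rz + (-load$axial_force)) / load$axial_force
  list(pair_force = pair_force, pair_area = pair_area,
       pair_anterior_share = pair_anterior_share,
       max_penetration = if (length(state$gaps)) max(0, -min(state$gaps)) else 0,
       tibial_reaction = rz,
       balance_error = balance_err)
}
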