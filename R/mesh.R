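# Tetrahedral mesh primitives: structured generation (mapped hex grids split
# into conforming Kuhn tetrahedra, prism core fans), watertight boundary
# extraction, divergence-theorem volumes, and exact conforming splits along
# level sets of a nodal scalar field.
#
# Conventions: nodes are an n x 3 matrix in mm; tets are an m x 4 integer
# matrix with positive signed volume det(b-a, c-a, d-a) > 0; outward boundary
# faces of tet (a,b,c,d) are (a,c,b), (a,b,d), (b,c,d), (a,d,c).

#' Construct a tetrahedral mesh object
#'
#' @param nodes numeric matrix (n x 3), coordinates in mm.
#' @param tets integer matrix (m x 4), node indices, positively oriented.
#' @param region character vector of length m, region tag per element.
#' @param fields optional numeric matrix (n x k) of nodal attribute fields
#'   (e.g. structured parameters rho/theta/zeta) interpolated across splits.
#' @return object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, region, fields = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(tets) == 4L, length(region) == nrow(tets))
  if (!is.null(fields)) {
    fields <- as.matrix(fields)
    stopifnot(nrow(fields) == nrow(nodes))
  }
  structure(list(nodes = nodes, tets = tets, region = as.character(region),
                 fields = fields),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets, regions: %s\n",
              nrow(x$nodes), nrow(x$tets),
              paste(unique(x$region), collapse = ", ")))
  invisible(x)
}

#' Signed tetrahedron volumes
#'
#' @param nodes node coordinate matrix.
#' @param tets element connectivity matrix.
#' @return numeric vector of signed volumes (mm^3).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE] - a
  c <- nodes[tets[, 3L], , drop = FALSE] - a
  d <- nodes[tets[, 4L], , drop = FALSE] - a
  (b[, 1L] * (c[, 2L] * d[, 3L] - c[, 3L] * d[, 2L]) -
   b[, 2L] * (c[, 1L] * d[, 3L] - c[, 3L] * d[, 1L]) +
   b[, 3L] * (c[, 1L] * d[, 2L] - c[, 2L] * d[, 1L])) / 6
}

fix_tet_orientation <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
  }
  tets
}

# All four outward-oriented faces of every tet, as an (4m x 3) matrix.
tet_faces <- function(tets) {
  rbind(tets[, c(1L, 3L, 2L)],
        tets[, c(1L, 2L, 4L)],
        tets[, c(2L, 3L, 4L)],
        tets[, c(1L, 4L, 3L)])
}

#' Extract the oriented boundary surface of a tet mesh
#'
#' Faces belonging to exactly one tetrahedron form the boundary; orientation
#' (outward) is inherited from the positively oriented elements, so the result
#' is watertight and consistently oriented whenever the mesh is conforming.
#'
#' @param mesh a `tet_mesh`.
#' @param label region label to attach to the surface.
#' @return a `surface_mesh`.
#' @export
boundary_surface <- function(mesh, label = "boundary") {
  faces <- tet_faces(mesh$tets)
  key <- face_key(faces)
  cnt <- table(key)
  keep <- cnt[key] == 1L
  surface_mesh(mesh$nodes, faces[keep, , drop = FALSE], label = label,
               compact = TRUE)
}

face_key <- function(faces) {
  lo <- pmin(faces[, 1L], faces[, 2L], faces[, 3L])
  hi <- pmax(faces[, 1L], faces[, 2L], faces[, 3L])
  mid <- faces[, 1L] + faces[, 2L] + faces[, 3L] - lo - hi
  paste(lo, mid, hi, sep = "/")
}

#' Construct a triangulated surface mesh
#'
#' @param vertices numeric matrix (n x 3) in mm.
#' @param triangles integer matrix (m x 3) of vertex index triples.
#' @param label region name.
#' @param compact drop vertices not referenced by any triangle.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, label = "surface",
                         compact = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(triangles) <- "integer"
  if (compact) {
    used <- sort(unique(as.vector(triangles)))
    remap <- integer(nrow(vertices))
    remap[used] <- seq_along(used)
    vertices <- vertices[used, , drop = FALSE]
    triangles <- matrix(remap[triangles], ncol = 3L)
  }
  structure(list(vertices = vertices, triangles = triangles, label = label),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh '%s': %d vertices, %d triangles\n",
              x$label, nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Triangle areas of a surface mesh
#' @param surface a `surface_mesh`.
#' @return numeric vector of areas (mm^2).
#' @export
triangle_areas <- function(surface) {
  v <- surface$vertices
  tr <- surface$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Outward unit normals of surface triangles
#' @param surface a `surface_mesh`.
#' @return m x 3 matrix of unit normals.
#' @export
triangle_normals <- function(surface) {
  v <- surface$vertices
  tr <- surface$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  n / sqrt(rowSums(n^2))
}

#' Audit a surface mesh for watertightness
#'
#' Checks that every edge is shared by exactly two triangles with opposite
#' direction (closed, consistently oriented 2-manifold) and that no triangle
#' is degenerate.
#'
#' @param surface a `surface_mesh`.
#' @param area_tol triangles with area below this are flagged degenerate.
#' @return list with logical `closed`, `oriented`, `degenerate` count and
#'   overall `watertight`.
#' @export
mesh_audit <- function(surface, area_tol = 1e-10) {
  tr <- surface$triangles
  edges <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  key_dir <- paste(edges[, 1L], edges[, 2L])
  key_und <- paste(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
  und_tab <- table(key_und)
  closed <- all(und_tab == 2L)
  oriented <- !any(duplicated(key_dir)) && closed
  ndeg <- sum(triangle_areas(surface) < area_tol)
  list(closed = closed, oriented = oriented, degenerate = ndeg,
       watertight = closed && oriented && ndeg == 0L)
}

#' Enclosed volume of a closed oriented surface (divergence theorem)
#'
#' Signed volume `sum det(v1, v2, v3) / 6`; positive for outward orientation.
#'
#' @param solid a `surface_mesh`, `tet_mesh` or `solid_region`.
#' @return volume in mm^3.
#' @export
compute_volume <- function(solid) {
  if (inherits(solid, "solid_region")) solid <- solid$boundary
  if (inherits(solid, "tet_mesh")) return(sum(tet_volumes(solid$nodes, solid$tets)))
  stopifnot(inherits(solid, "surface_mesh"))
  audit <- mesh_audit(solid)
  if (!audit$closed)
    stop("compute_volume: surface is not closed (open mesh)")
  v <- solid$vertices
  tr <- solid$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  b <- v[tr[, 2L], , drop = FALSE]
  c <- v[tr[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) -
      a[, 2L] * (b[, 1L] * c[, 3L] - b[, 3L] * c[, 1L]) +
      a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])) / 6
}

#' Brute-force voxel-count volume of a closed surface
#'
#' Rasterizes the solid on a cubic lattice of spacing `h` by vertical
#' ray-casting parity and counts interior voxel centres. Independent check of
#' the divergence-theorem volume.
#'
#' @param surface closed `surface_mesh`.
#' @param h voxel edge length in mm.
#' @return volume estimate in mm^3.
#' @export
voxelize_volume <- function(surface, h = 0.2) {
  v <- surface$vertices
  tr <- surface$triangles
  xr <- range(v[, 1L]); yr <- range(v[, 2L]); zr <- range(v[, 3L])
  xs <- seq(xr[1L] + h / 2, xr[2L], by = h)
  ys <- seq(yr[1L] + h / 2, yr[2L], by = h)
  ncol_x <- length(xs); ncol_y <- length(ys)
  # per-column list of surface crossing heights
  cross_col <- vector("list", ncol_x * ncol_y)
  for (t in seq_len(nrow(tr))) {
    p1 <- v[tr[t, 1L], ]; p2 <- v[tr[t, 2L], ]; p3 <- v[tr[t, 3L], ]
    ix <- which(xs >= min(p1[1L], p2[1L], p3[1L]) - h &
                xs <= max(p1[1L], p2[1L], p3[1L]) + h)
    iy <- which(ys >= min(p1[2L], p2[2L], p3[2L]) - h &
                ys <= max(p1[2L], p2[2L], p3[2L]) + h)
    if (!length(ix) || !length(iy)) next
    gx <- rep(xs[ix], times = length(iy))
    gy <- rep(ys[iy], each = length(ix))
    # barycentric in the xy-projection
    d <- (p2[2L] - p3[2L]) * (p1[1L] - p3[1L]) +
         (p3[1L] - p2[1L]) * (p1[2L] - p3[2L])
    if (abs(d) < 1e-14) next
    l1 <- ((p2[2L] - p3[2L]) * (gx - p3[1L]) +
           (p3[1L] - p2[1L]) * (gy - p3[2L])) / d
    l2 <- ((p3[2L] - p1[2L]) * (gx - p3[1L]) +
           (p1[1L] - p3[1L]) * (gy - p3[2L])) / d
    l3 <- 1 - l1 - l2
    inside <- l1 >= 0 & l2 >= 0 & l3 > 0  # half-open to avoid double edges
    if (!any(inside)) next
    zc <- l1[inside] * p1[3L] + l2[inside] * p2[3L] + l3[inside] * p3[3L]
    cols <- (rep(iy, each = length(ix))[inside] - 1L) * ncol_x +
            rep(ix, times = length(iy))[inside]
    for (k in seq_along(cols)) {
      cc <- cols[k]
      cross_col[[cc]] <- c(cross_col[[cc]], zc[k])
    }
  }
  nvox <- 0L
  zs0 <- zr[1L] + h / 2
  for (cc in seq_along(cross_col)) {
    z <- cross_col[[cc]]
    if (length(z) < 2L) next
    z <- sort(z)
    # pair entries/exits; odd counts (grazing) are dropped conservatively
    np <- length(z) %/% 2L
    for (p in seq_len(np)) {
      z1 <- z[2L * p - 1L]; z2 <- z[2L * p]
      k1 <- ceiling((z1 - zs0) / h)
      k2 <- floor((z2 - zs0) / h)
      if (k2 >= k1) nvox <- nvox + (k2 - k1 + 1L)
    }
  }
  nvox * h^3
}

# ---------------------------------------------------------------------------
# Structured generation

# Kuhn subdivision of one hex given its 8 corner ids in v[ijk] binary order
# c(v000, v100, v010, v110, v001, v101, v011, v111). Returns 6 x 4 matrix.
kuhn_tets <- function(h) {
  idx <- function(i, j, k) h[1L + i + 2L * j + 4L * k]
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  out <- matrix(0L, 6L, 4L)
  for (p in seq_along(perms)) {
    step <- c(0L, 0L, 0L)
    verts <- integer(4L)
    verts[1L] <- idx(0L, 0L, 0L)
    for (q in 1:3) {
      step[perms[[p]][q]] <- 1L
      verts[q + 1L] <- idx(step[1L], step[2L], step[3L])
    }
    out[p, ] <- verts
  }
  out
}

# Fixed prism decomposition with diagonals a-b', b-c', a-c'
# (bottom a,b,c; top ap,bp,cp). Conforms with Kuhn hexes and with rotated
# copies of itself around a core fan.
prism_tets <- function(a, b, c, ap, bp, cp) {
  rbind(c(a, b, c, cp),
        c(a, b, cp, bp),
        c(a, bp, cp, ap))
}

#' Structured tet mesh of a mapped elliptic annulus / disc
#'
#' Generates nodes on an elliptic-polar grid (x,y) = centre + (A*rho*cos th,
#' B*rho*sin th) between two height surfaces, and splits the hex cells into
#' conforming tetrahedra. `rho_in = 0` produces a solid disc with a prism
#' core fan. Nodal fields `rho`, `theta`, `zeta` are stored for downstream
#' partitioning.
#'
#' @param centre length-2 (x, y) centre in mm.
#' @param semi_axes length-2 outer semi-axes (A, B) in mm.
#' @param rho_in inner hole parameter in [0, 1).
#' @param z_bot,z_top functions of (x, y) giving bottom/top heights in mm.
#' @param n_rho,n_theta,n_zeta grid divisions.
#' @param region region tag.
#' @param rho_values optional explicit radial grid (overrides n_rho).
#' @return a `tet_mesh` with fields rho, theta, zeta.
#' @export
annulus_mesh <- function(centre, semi_axes, rho_in, z_bot, z_top,
                         n_rho = 8L, n_theta = 36L, n_zeta = 2L,
                         region = "solid", rho_values = NULL) {
  stopifnot(rho_in >= 0, rho_in < 1)
  if (is.null(rho_values)) {
    rho_values <- if (rho_in > 0) seq(rho_in, 1, length.out = n_rho + 1L)
                  else seq(0, 1, length.out = n_rho + 1L)[-1L]
  }
  has_core <- rho_in == 0
  nr <- length(rho_values)
  nt <- as.integer(n_theta)
  nz <- as.integer(n_zeta) + 1L
  thetas <- seq(0, 2 * pi, length.out = nt + 1L)[-(nt + 1L)]
  zetas <- seq(0, 1, length.out = nz)

  # ring nodes: id(i, j, k) for i radial, j angular (periodic), k vertical
  nid <- function(i, j, k) ((k - 1L) * nt + ((j - 1L) %% nt)) * nr + i
  n_ring <- nr * nt * nz
  rho_g <- rep(rho_values, times = nt * nz)
  th_g <- rep(rep(thetas, each = nr), times = nz)
  ze_g <- rep(zetas, each = nr * nt)
  xg <- centre[1L] + semi_axes[1L] * rho_g * cos(th_g)
  yg <- centre[2L] + semi_axes[2L] * rho_g * sin(th_g)
  if (has_core) {
    ax_id <- n_ring + seq_len(nz)          # axis nodes, one per level
    xg <- c(xg, rep(centre[1L], nz))
    yg <- c(yg, rep(centre[2L], nz))
    rho_g <- c(rho_g, rep(0, nz))
    th_g <- c(th_g, rep(0, nz))
    ze_g <- c(ze_g, zetas)
  }
  zb <- z_bot(xg, yg)
  zt <- z_top(xg, yg)
  if (any(zt - zb <= 0))
    stop("annulus_mesh: non-positive thickness encountered")
  zg <- zb + ze_g * (zt - zb)
  nodes <- cbind(x = xg, y = yg, z = zg)

  # cells in the posterior half (theta > pi) are built as mirror images of
  # the anterior pattern, so the tetrahedral connectivity is exactly
  # symmetric about the anterior-posterior plane (mirrored resection models
  # then solve on mirror-identical discretizations); the seam diagonals at
  # theta = 0 and pi coincide by construction
  tets_list <- vector("list", 0L)
  for (k in seq_len(nz - 1L)) {
    for (j in seq_len(nt)) {
      mirrored <- (j - 0.5) / nt > 0.5
      j1 <- if (mirrored) j + 1L else j
      j2 <- if (mirrored) j else j + 1L
      if (has_core) {
        a <- ax_id[k]; ap <- ax_id[k + 1L]
        b <- nid(1L, j1, k); c <- nid(1L, j2, k)
        bp <- nid(1L, j1, k + 1L); cp <- nid(1L, j2, k + 1L)
        tets_list[[length(tets_list) + 1L]] <- prism_tets(a, b, c, ap, bp, cp)
      }
      if (nr > 1L) {
        for (i in seq_len(nr - 1L)) {
          h <- c(nid(i, j1, k),  nid(i + 1L, j1, k),
                 nid(i, j2, k),  nid(i + 1L, j2, k),
                 nid(i, j1, k + 1L),  nid(i + 1L, j1, k + 1L),
                 nid(i, j2, k + 1L),  nid(i + 1L, j2, k + 1L))
          tets_list[[length(tets_list) + 1L]] <- kuhn_tets(h)
        }
      }
    }
  }
  tets <- do.call(rbind, tets_list)
  tets <- fix_tet_orientation(nodes, tets)
  tet_mesh(nodes, tets, rep(region, nrow(tets)),
           fields = cbind(rho = rho_g, theta = th_g, zeta = ze_g))
}

#' Structured tet mesh of a rectilinear box
#'
#' @param xs,ys,zs strictly increasing coordinate vectors (mm).
#' @param region region tag.
#' @return a `tet_mesh` with fields x0, y0, z0 (reference coordinates).
#' @export
box_mesh <- function(xs, ys, zs, region = "block") {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nid <- function(i, j, k) ((k - 1L) * ny + (j - 1L)) * nx + i
  nodes <- cbind(x = rep(xs, times = ny * nz),
                 y = rep(rep(ys, each = nx), times = nz),
                 z = rep(zs, each = nx * ny))
  tets_list <- vector("list", (nx - 1L) * (ny - 1L) * (nz - 1L))
  idx <- 0L
  for (k in seq_len(nz - 1L)) for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    h <- c(nid(i, j, k), nid(i + 1L, j, k), nid(i, j + 1L, k), nid(i + 1L, j + 1L, k),
           nid(i, j, k + 1L), nid(i + 1L, j, k + 1L), nid(i, j + 1L, k + 1L),
           nid(i + 1L, j + 1L, k + 1L))
    idx <- idx + 1L
    tets_list[[idx]] <- kuhn_tets(h)
  }
  tets <- do.call(rbind, tets_list)
  tets <- fix_tet_orientation(nodes, tets)
  tet_mesh(nodes, tets, rep(region, nrow(tets)), fields = nodes)
}

#' Merge tet meshes into one (disjoint node sets)
#' @param meshes list of `tet_mesh` objects.
#' @return a `tet_mesh`; fields are kept when all inputs share column names.
#' @export
merge_meshes <- function(meshes) {
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$nodes), 0L)))
  nodes <- do.call(rbind, lapply(meshes, `[[`, "nodes"))
  tets <- do.call(rbind, lapply(seq_along(meshes), function(i)
    meshes[[i]]$tets + offs[i]))
  region <- unlist(lapply(meshes, `[[`, "region"))
  flds <- lapply(meshes, `[[`, "fields")
  fields <- NULL
  if (!any(vapply(flds, is.null, TRUE))) {
    cn <- lapply(flds, colnames)
    if (length(unique(vapply(cn, paste, "", collapse = ","))) == 1L)
      fields <- do.call(rbind, flds)
  }
  tet_mesh(nodes, tets, region, fields = fields)
}

# ---------------------------------------------------------------------------
# Level-set volume and conforming split

# guarded ratio for the stable volume-fraction formulas
.gr <- function(num, den) ifelse(den > 1e-300 & den > abs(num) * 1e-14,
                                 pmin(pmax(num / den, 0), 1), 0.5)

#' Volume of the sublevel region {phi < iso} of a tet mesh
#'
#' Exact for a nodal field interpolated linearly within each element; uses
#' stable per-case closed forms.
#'
#' @param mesh a `tet_mesh`.
#' @param phi numeric nodal field (length = number of nodes).
#' @param iso level value.
#' @return volume in mm^3.
#' @export
volume_below_levelset <- function(mesh, phi, iso) {
  vals <- matrix(phi[mesh$tets], ncol = 4L)
  # 4-element sorting network, vectorized over rows
  w1 <- pmin(vals[, 1L], vals[, 2L]); w2 <- pmax(vals[, 1L], vals[, 2L])
  w3 <- pmin(vals[, 3L], vals[, 4L]); w4 <- pmax(vals[, 3L], vals[, 4L])
  a <- pmin(w1, w3); x3 <- pmax(w1, w3)
  x2 <- pmin(w2, w4); d <- pmax(w2, w4)
  b <- pmin(x2, x3); c <- pmax(x2, x3)
  V <- tet_volumes(mesh$nodes, mesh$tets)
  t <- iso
  frac <- numeric(length(V))
  frac[t >= d] <- 1
  i1 <- t > a & t <= b
  if (any(i1)) {
    frac[i1] <- .gr(t - a[i1], b[i1] - a[i1]) *
                .gr(t - a[i1], c[i1] - a[i1]) *
                .gr(t - a[i1], d[i1] - a[i1])
  }
  i2 <- t > b & t < c
  if (any(i2)) {
    u <- .gr(t - b[i2], c[i2] - b[i2])
    v <- .gr(t - b[i2], d[i2] - b[i2])
    s <- .gr(t - a[i2], c[i2] - a[i2])
    w <- .gr(t - a[i2], d[i2] - a[i2])
    frac[i2] <- u * v + s * v * (1 - u) + s * w * (1 - v)
  }
  i3 <- t >= c & t < d
  if (any(i3)) {
    frac[i3] <- 1 - .gr(d[i3] - t, d[i3] - a[i3]) *
                    .gr(d[i3] - t, d[i3] - b[i3]) *
                    .gr(d[i3] - t, d[i3] - c[i3])
  }
  sum(frac * V)
}

# split one quad (v1,v2,v3,v4 cyclic) into two triangles by the diagonal
# through its minimum global vertex id (conforming across pieces).
quad_split <- function(q) {
  if (min(q[1L], q[3L]) < min(q[2L], q[4L]))
    rbind(q[c(1L, 2L, 3L)], q[c(1L, 3L, 4L)])
  else
    rbind(q[c(2L, 3L, 4L)], q[c(2L, 4L, 1L)])
}

#' Conforming split of a tet mesh along a level set of a nodal field
#'
#' Cuts every element crossing `phi = iso` with the linear interpolant of
#' `phi`, producing a conforming tetrahedral mesh in which each element lies
#' entirely on one side. Cut vertices are created once per mesh edge, so the
#' result is watertight; nodal fields are linearly interpolated onto new
#' vertices.
#'
#' @param mesh a `tet_mesh`.
#' @param phi nodal field.
#' @param iso level value.
#' @param snap_tol nodes with |phi - iso| below this are treated as on the cut.
#' @return list(mesh, phi, side) where side is "below"/"above" per element.
#' @export
split_by_levelset <- function(mesh, phi, iso,
                              snap_tol = 1e-9 * max(1e-12, diff(range(phi)))) {
  nodes <- mesh$nodes
  fields <- mesh$fields
  s <- phi - iso
  s[abs(s) < snap_tol] <- 0
  tets <- mesh$tets
  sv <- matrix(s[tets], ncol = 4L)
  nb <- rowSums(sv < 0)
  na <- rowSums(sv > 0)
  crossing <- which(nb > 0L & na > 0L)

  new_tets <- list()
  new_region <- list()
  new_side <- list()
  keep <- setdiff(seq_len(nrow(tets)), crossing)
  if (length(keep)) {
    new_tets[[1L]] <- tets[keep, , drop = FALSE]
    new_region[[1L]] <- mesh$region[keep]
    new_side[[1L]] <- ifelse(nb[keep] > 0L, "below", "above")
  }

  if (length(crossing)) {
    edge_env <- new.env(hash = TRUE, parent = emptyenv())
    extra_nodes <- list(); extra_phi <- list(); extra_fields <- list()
    n_nodes <- nrow(nodes)
    cut_point <- function(i, j) {
      key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
      id <- edge_env[[key]]
      if (!is.null(id)) return(id)
      ti <- s[i] / (s[i] - s[j])
      p <- nodes[i, ] + ti * (nodes[j, ] - nodes[i, ])
      n_nodes <<- n_nodes + 1L
      extra_nodes[[length(extra_nodes) + 1L]] <<- p
      extra_phi[[length(extra_phi) + 1L]] <<- iso
      if (!is.null(fields))
        extra_fields[[length(extra_fields) + 1L]] <<-
          fields[i, ] + ti * (fields[j, ] - fields[i, ])
      edge_env[[key]] <- n_nodes
      n_nodes
    }
    add_piece <- function(tt, reg, side) {
      new_tets[[length(new_tets) + 1L]] <<- tt
      new_region[[length(new_region) + 1L]] <<- rep(reg, nrow(tt))
      new_side[[length(new_side) + 1L]] <<- rep(side, nrow(tt))
    }
    n_base <- nrow(nodes)
    get_node <- function(i) {
      if (i <= n_base) nodes[i, ] else extra_nodes[[i - n_base]]
    }
    get_phi <- function(i) {
      if (i <= n_base) phi[i] else extra_phi[[i - n_base]]
    }
    get_fields <- function(i) {
      if (i <= n_base) fields[i, ] else extra_fields[[i - n_base]]
    }
    # Steiner split of a (possibly skew) prism: bottom tri (p1,p2,p3), top
    # (q1,q2,q3) with pi below qi; centroid apex, quad faces by quad_split.
    steiner_id <- function(vids) {
      pts <- vapply(vids, get_node, numeric(3L))
      n_nodes <<- n_nodes + 1L
      extra_nodes[[length(extra_nodes) + 1L]] <<- rowMeans(pts)
      extra_phi[[length(extra_phi) + 1L]] <<-
        mean(vapply(vids, get_phi, 0))
      if (!is.null(fields))
        extra_fields[[length(extra_fields) + 1L]] <<-
          rowMeans(vapply(vids, get_fields, numeric(ncol(fields))))
      n_nodes
    }
    nodes_all <- function() {
      if (length(extra_nodes)) rbind(nodes, do.call(rbind, extra_nodes))
      else nodes
    }
    phi_all <- function() c(phi, unlist(extra_phi))
    fields_all <- function() {
      if (length(extra_fields)) rbind(fields, do.call(rbind, extra_fields))
      else fields
    }
    prism_steiner <- function(p, q, reg, side) {
      ctr <- steiner_id(c(p, q))
      tt <- rbind(c(p[1L], p[3L], p[2L], ctr),   # bottom, inward
                  c(q[1L], q[2L], q[3L], ctr))   # top, inward
      quads <- list(c(p[1L], p[2L], q[2L], q[1L]),
                    c(p[2L], p[3L], q[3L], q[2L]),
                    c(p[3L], p[1L], q[1L], q[3L]))
      for (qd in quads) {
        trs <- quad_split(qd)
        tt <- rbind(tt, cbind(trs, ctr))
      }
      add_piece(tt, reg, side)
    }
    for (e in crossing) {
      vid <- tets[e, ]
      sgn <- s[vid]
      B <- vid[sgn < 0]; A <- vid[sgn > 0]; O <- vid[sgn == 0]
      reg <- mesh$region[e]
      if (length(B) == 1L && length(A) == 1L) {
        cp <- cut_point(B, A)
        add_piece(rbind(c(B, cp, O[1L], O[2L])), reg, "below")
        add_piece(rbind(c(A, cp, O[1L], O[2L])), reg, "above")
      } else if (length(B) == 1L && length(A) == 2L) {
        c1 <- cut_point(B, A[1L]); c2 <- cut_point(B, A[2L])
        add_piece(rbind(c(B, c1, c2, O)), reg, "below")
        trs <- quad_split(c(c1, A[1L], A[2L], c2))
        add_piece(cbind(trs, O), reg, "above")
      } else if (length(B) == 2L && length(A) == 1L) {
        c1 <- cut_point(A, B[1L]); c2 <- cut_point(A, B[2L])
        add_piece(rbind(c(A, c1, c2, O)), reg, "above")
        trs <- quad_split(c(c1, B[1L], B[2L], c2))
        add_piece(cbind(trs, O), reg, "below")
      } else if (length(B) == 1L && length(A) == 3L) {
        c1 <- cut_point(B, A[1L]); c2 <- cut_point(B, A[2L]); c3 <- cut_point(B, A[3L])
        add_piece(rbind(c(B, c1, c2, c3)), reg, "below")
        prism_steiner(c(c1, c2, c3), A[1:3], reg, "above")
      } else if (length(B) == 3L && length(A) == 1L) {
        c1 <- cut_point(A, B[1L]); c2 <- cut_point(A, B[2L]); c3 <- cut_point(A, B[3L])
        add_piece(rbind(c(A, c1, c2, c3)), reg, "above")
        prism_steiner(c(c1, c2, c3), B[1:3], reg, "below")
      } else if (length(B) == 2L && length(A) == 2L) {
        c11 <- cut_point(B[1L], A[1L]); c12 <- cut_point(B[1L], A[2L])
        c21 <- cut_point(B[2L], A[1L]); c22 <- cut_point(B[2L], A[2L])
        prism_steiner(c(B[1L], c11, c12), c(B[2L], c21, c22), reg, "below")
        prism_steiner(c(A[1L], c11, c21), c(A[2L], c12, c22), reg, "above")
      } else {
        stop("split_by_levelset: unhandled case")
      }
    }
    nodes <- nodes_all()
    phi <- phi_all()
    fields <- fields_all()
  }
  tets_out <- do.call(rbind, new_tets)
  storage.mode(tets_out) <- "integer"
  tets_out2 <- fix_tet_orientation(nodes, tets_out)
  out <- tet_mesh(nodes, tets_out2, unlist(new_region), fields = fields)
  list(mesh = out, phi = phi, side = unlist(new_side))
}

#' Keep a subset of elements (nodes compacted)
#' @param mesh a `tet_mesh`.
#' @param keep logical or integer element selector.
#' @return a `tet_mesh`.
#' @export
subset_mesh <- function(mesh, keep) {
  tets <- mesh$tets[keep, , drop = FALSE]
  region <- mesh$region[keep]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  tet_mesh(mesh$nodes[used, , drop = FALSE],
           matrix(remap[tets], ncol = 4L),
           region,
           fields = if (!is.null(mesh$fields)) mesh$fields[used, , drop = FALSE])
}
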