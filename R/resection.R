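# Virtual meniscectomy: partition the discoid meniscus by volume ratio into
# five concentric zones (15/15/15/15/40 % from the inner free margin to the
# peripheral rim), split anterior/posterior by an equal-volume plane, and
# generate the 15-model residual family by innermost-first zone removal with
# smoothed junctions between unequally resected halves.

#' Partition scheme for the meniscus zones
#'
#' @param ring_fractions volume fractions from the innermost zone to the
#'   peripheral rim; must sum to 1.
#' @return object of class `partition_scheme`.
#' @export
partition_scheme <- function(ring_fractions = c(0.15, 0.15, 0.15, 0.15, 0.40)) {
  if (any(ring_fractions <= 0))
    stop("partition_scheme: all ring fractions must be positive")
  if (abs(sum(ring_fractions) - 1) > 1e-12)
    stop("partition_scheme: ring fractions must sum to 1")
  structure(list(ring_fractions = ring_fractions,
                 ap_split_rule = "equal_volume_plane"),
            class = "partition_scheme")
}

#' Partition a meniscus into concentric volume-ratio zones
#'
#' Zone boundaries are inward offsets of the outer margin, found by root
#' bracketing on the offset parameter until each cumulative volume (measured
#' from the peripheral rim inward) matches its target; the mesh is then cut
#' conformingly along each boundary, so realized fractions match targets to
#' solver tolerance.
#'
#' @param meniscus a `solid_region` carrying the structured radial parameter
#'   `rho` in its nodal fields (as produced by the meniscus builders).
#' @param scheme a `partition_scheme`.
#' @return object of class `meniscus_partition`: the cut mesh, per-element
#'   ring index (1 = innermost), boundary offsets, realized volumes.
#' @export
partition_rings <- function(meniscus, scheme = partition_scheme()) {
  stopifnot(inherits(meniscus, "solid_region"))
  mesh <- meniscus$mesh
  if (is.null(mesh$fields) || !"rho" %in% colnames(mesh$fields))
    stop("partition_rings: meniscus mesh lacks the structured radial parameter")
  fr <- scheme$ring_fractions
  nring <- length(fr)
  V <- sum(tet_volumes(mesh$nodes, mesh$tets))
  if (nring == 1L) {
    return(structure(list(mesh = mesh, ring = rep(1L, nrow(mesh$tets)),
                          side = NULL, boundaries = numeric(0),
                          ring_volumes = V, source_volume = V,
                          scheme = scheme, split_plane = NULL,
                          meta = meniscus$meta, tag = meniscus$tag),
                     class = "meniscus_partition"))
  }
  # fast path for meniscus solids built by this package: regenerate the
  # structured mesh with the zone boundaries as radial grid surfaces (no
  # element cutting, no slivers), iterating the boundary radii until the
  # whole-shell volumes hit the targets
  if (!is.null(meniscus$meta$config)) {
    part <- .partition_by_remesh(meniscus, scheme)
    if (!is.null(part)) return(part)
  }
  # cumulative targets measured from the periphery inward; rho decreases
  # inward, so volume(rho > u) is the peripheral cumulative volume
  cum_peripheral <- cumsum(rev(fr))[-nring]   # e.g. 0.40, 0.55, 0.70, 0.85
  phi <- mesh$fields[, "rho"]
  rng <- range(phi)
  boundaries <- numeric(length(cum_peripheral))
  for (k in seq_along(cum_peripheral)) {
    target <- cum_peripheral[k] * V
    f <- function(u) {
      (V - volume_below_levelset(mesh, mesh$fields[, "rho"], u)) - target
    }
    lo <- rng[1L] + 1e-9; hi <- rng[2L] - 1e-9
    if (f(lo) * f(hi) > 0)
      stop(sprintf(paste0("partition_rings: cannot bracket cumulative fraction %.3f;",
                          " achievable range [%.3f, %.3f]"),
                   cum_peripheral[k],
                   1 - volume_below_levelset(mesh, mesh$fields[, "rho"], hi) / V,
                   1 - volume_below_levelset(mesh, mesh$fields[, "rho"], lo) / V))
    u <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    boundaries[k] <- u
    sp <- split_by_levelset(mesh, mesh$fields[, "rho"], u)
    mesh <- sp$mesh
  }
  # ring index per element: rim (inside no boundary) = nring, innermost = 1
  el_rho <- rowMeans(matrix(mesh$fields[mesh$tets, "rho"], ncol = 4L))
  bs <- sort(boundaries, decreasing = TRUE)
  inside_count <- vapply(el_rho, function(r) sum(r < bs), 0L)
  ring <- nring - inside_count
  vols <- tet_volumes(mesh$nodes, mesh$tets)
  ring_volumes <- vapply(seq_len(nring), function(k) sum(vols[ring == k]), 0)
  structure(list(mesh = mesh, ring = as.integer(ring), side = NULL,
                 boundaries = bs, ring_volumes = ring_volumes,
                 source_volume = V, scheme = scheme, split_plane = NULL,
                 meta = meniscus$meta, tag = meniscus$tag),
            class = "meniscus_partition")
}

# Remesh-based partition: boundary radii become radial grid surfaces.
.partition_by_remesh <- function(meniscus, scheme) {
  meta <- meniscus$meta
  cfg <- meta$config
  fr <- scheme$ring_fractions
  nring <- length(fr)
  cum_per <- cumsum(rev(fr))[-nring]    # peripheral cumulative targets
  mesh <- meniscus$mesh
  rho <- mesh$fields[, "rho"]
  rng <- range(rho)
  V <- sum(tet_volumes(mesh$nodes, mesh$tets))
  u <- vapply(cum_per, function(Ft) {
    stats::uniroot(function(uu)
      (V - volume_below_levelset(mesh, mesh$fields[, "rho"], uu)) - Ft * V,
      c(rng[1L] + 1e-9, rng[2L] - 1e-9), tol = 1e-10)$root
  }, 0)
  dv <- .meniscus_divisions(cfg, meta$semi_axes, meta$rho_in)
  base <- if (meta$rho_in > 0)
            seq(meta$rho_in, 1, length.out = dv$n_rho + 1L)
          else seq(0, 1, length.out = dv$n_rho + 1L)[-1L]
  spacing <- mean(diff(base))
  sol <- NULL
  for (it in 1:12) {
    keep <- vapply(base, function(b) all(abs(b - u) > 0.35 * spacing), TRUE)
    rho_values <- sort(unique(c(base[keep], u)))
    sol <- .build_meniscus(cfg, meta$side, meta$rho_in, meta$tag,
                           rho_values = rho_values)
    msh <- sol$mesh
    vols <- tet_volumes(msh$nodes, msh$tets)
    el_rho <- rowMeans(matrix(msh$fields[msh$tets, "rho"], ncol = 4L))
    Vm <- sum(vols)
    realized <- vapply(u, function(uu) sum(vols[el_rho > uu]) / Vm, 0)
    err <- realized - cum_per
    if (max(abs(err)) < 1e-7) break
    # Newton step with the shell density from the level-set volume derivative
    for (k in seq_along(u)) {
      d <- 0.25 * spacing
      dens <- (volume_below_levelset(msh, msh$fields[, "rho"], u[k] + d) -
               volume_below_levelset(msh, msh$fields[, "rho"], u[k] - d)) /
              (2 * d) / Vm
      u[k] <- min(max(u[k] + err[k] / max(dens, 1e-9),
                      rng[1L] + 1e-6), rng[2L] - 1e-6)
    }
    u <- sort(u, decreasing = TRUE)   # matches the peripheral target order
  }
  msh <- sol$mesh
  vols <- tet_volumes(msh$nodes, msh$tets)
  el_rho <- rowMeans(matrix(msh$fields[msh$tets, "rho"], ncol = 4L))
  bs <- sort(u, decreasing = TRUE)
  inside_count <- vapply(el_rho, function(r) sum(r < bs), 0L)
  ring <- nring - inside_count
  ring_volumes <- vapply(seq_len(nring), function(k) sum(vols[ring == k]), 0)
  structure(list(mesh = msh, ring = as.integer(ring), side = NULL,
                 boundaries = bs, ring_volumes = ring_volumes,
                 source_volume = sum(vols), scheme = scheme,
                 split_plane = NULL, meta = sol$meta, tag = sol$tag),
            class = "meniscus_partition")
}

#' @export
print.meniscus_partition <- function(x, ...) {
  cat(sprintf("meniscus_partition: %d rings, source volume %.1f mm^3\n",
              length(x$ring_volumes), x$source_volume))
  cat("ring fractions (inner->rim):",
      paste(sprintf("%.3f", x$ring_volumes / x$source_volume), collapse = " "),
      "\n")
  if (!is.null(x$side))
    cat(sprintf("AP split at y = %.3f mm; anterior fraction %.4f\n",
                x$split_plane, x$anterior_fraction))
  invisible(x)
}

#' Split a partitioned meniscus into anterior and posterior halves
#'
#' Positions a plane normal to the anterior-posterior axis by root bracketing
#' so the anterior and posterior total volumes are equal, then cuts the mesh
#' conformingly along it; every ring is split into anterior and posterior
#' sub-regions (10 region tags for the default scheme).
#'
#' @param partition a `meniscus_partition` from [partition_rings()].
#' @return the partition with `side` ("anterior"/"posterior" per element) and
#'   `split_plane` (y position, mm) filled in.
#' @export
split_anterior_posterior <- function(partition) {
  stopifnot(inherits(partition, "meniscus_partition"))
  mesh <- partition$mesh
  V <- sum(tet_volumes(mesh$nodes, mesh$tets))
  yr <- range(mesh$nodes[, 2L])
  f <- function(y0) volume_below_levelset(mesh, mesh$nodes[, 2L], y0) - V / 2
  y0 <- stats::uniroot(f, c(yr[1L] + 1e-9, yr[2L] - 1e-9), tol = 1e-10)$root
  # if the plane is already a mesh plane (AP-symmetric meniscus with an even
  # angular grid), no cutting is needed
  yv <- matrix(mesh$nodes[mesh$tets, 2L], ncol = 4L)
  sn <- 1e-9 * max(1, diff(yr))
  crossing <- rowSums(yv < y0 - sn) > 0L & rowSums(yv > y0 + sn) > 0L
  if (!any(crossing)) {
    ctr_y <- rowMeans(yv)
    sp <- list(mesh = mesh, side = ifelse(ctr_y < y0, "below", "above"))
  } else {
    sp <- split_by_levelset(mesh, mesh$nodes[, 2L], y0)
  }
  # propagate ring tags: elements inherit from their parent; split_by_levelset
  # preserves element region but not our ring vector, so recompute from the
  # per-element mean rho against the stored boundaries
  mesh2 <- sp$mesh
  el_rho <- rowMeans(matrix(mesh2$fields[mesh2$tets, "rho"], ncol = 4L))
  bs <- partition$boundaries
  nring <- length(partition$ring_volumes)
  inside_count <- vapply(el_rho, function(r) sum(r < bs), 0L)
  ring <- nring - inside_count
  side <- ifelse(sp$side == "below", "posterior", "anterior")  # +y = anterior
  vols <- tet_volumes(mesh2$nodes, mesh2$tets)
  va <- sum(vols[side == "anterior"])
  vp <- sum(vols[side == "posterior"])
  partition$mesh <- mesh2
  partition$ring <- as.integer(ring)
  partition$side <- side
  partition$split_plane <- y0
  partition$anterior_fraction <- va / (va + vp)
  partition$ring_volumes <- vapply(seq_len(nring), function(k)
    sum(vols[ring == k]), 0)
  partition
}

#' Residual-fraction specification of one resection model
#'
#' @param anterior_fraction,posterior_fraction residual fractions, each in
#'   {1.00, 0.85, 0.70, 0.55, 0.40}; 1.00 pairs only with 1.00 and the
#'   anterior-posterior difference may not exceed 0.30.
#' @return object of class `resection_spec`.
#' @export
resection_spec <- function(anterior_fraction, posterior_fraction) {
  allowed <- c(1.00, 0.85, 0.70, 0.55, 0.40)
  ok <- function(x) any(abs(x - allowed) < 1e-9)
  if (!ok(anterior_fraction) || !ok(posterior_fraction))
    stop("resection_spec: fractions must be one of 1.00, 0.85, 0.70, 0.55, 0.40")
  if (abs(anterior_fraction - posterior_fraction) > 0.30 + 1e-9)
    stop("resection_spec: |anterior - posterior| must not exceed 0.30")
  if ((abs(anterior_fraction - 1) < 1e-9) != (abs(posterior_fraction - 1) < 1e-9))
    stop("resection_spec: the intact fraction 1.00 pairs only with 1.00")
  structure(list(anterior_fraction = anterior_fraction,
                 posterior_fraction = posterior_fraction),
            class = "resection_spec")
}

#' Canonical model name for a resection specification
#'
#' Residual percentages in the "NNaNNp" convention, e.g. anterior 85 % and
#' posterior 70 % residual volume gives "85a70p".
#'
#' @param spec a `resection_spec` (or two bare fractions).
#' @return character scalar.
#' @export
model_name <- function(spec) {
  sprintf("%da%dp", round(spec$anterior_fraction * 100),
          round(spec$posterior_fraction * 100))
}

#' Enumerate the 15-model residual family
#'
#' The intact meniscus plus every pair from {0.85, 0.70, 0.55, 0.40}^2 whose
#' anterior-posterior difference does not exceed 0.30.
#'
#' @return list of `resection_spec` objects, named by [model_name()].
#' @export
enumerate_family <- function() {
  fr <- c(0.85, 0.70, 0.55, 0.40)
  specs <- list(resection_spec(1, 1))
  for (a in fr) for (p in fr) {
    if (abs(a - p) <= 0.30 + 1e-9)
      specs[[length(specs) + 1L]] <- resection_spec(a, p)
  }
  names(specs) <- vapply(specs, model_name, "")
  specs
}

#' Resect a partitioned meniscus to a residual specification
#'
#' Removes whole innermost-zone sub-regions independently on the anterior and
#' posterior side (each step removes one 15 %-of-side zone half) until the
#' side's residual fraction matches the specification; the peripheral 40 %
#' rim is never removed. The result is watertight.
#'
#' @param partition an AP-split `meniscus_partition`.
#' @param spec a `resection_spec`.
#' @return object of class `resection_model`: canonical `name`, residual
#'   `solid`, realized volumes and fractions, `smoothing_applied` flag.
#' @export
resect <- function(partition, spec) {
  stopifnot(inherits(partition, "meniscus_partition"),
            inherits(spec, "resection_spec"))
  if (is.null(partition$side))
    stop("resect: partition must be split into anterior/posterior first")
  nring <- length(partition$ring_volumes)
  n_removable <- nring - 1L   # the peripheral rim is never removed
  step <- partition$scheme$ring_fractions[1L]
  n_rm <- function(fraction) {
    n <- (1 - fraction) / step
    ni <- as.integer(round(n))
    if (abs(n - ni) > 1e-6 || ni < 0L || ni > n_removable)
      stop(sprintf("resect: residual fraction %.2f is not reachable by whole-ring removal",
                   fraction))
    ni
  }
  na <- n_rm(spec$anterior_fraction)
  np <- n_rm(spec$posterior_fraction)
  remove <- (partition$side == "anterior" & partition$ring <= na) |
            (partition$side == "posterior" & partition$ring <= np)
  keep <- !remove
  mesh <- subset_mesh(partition$mesh, keep)
  vols_all <- tet_volumes(partition$mesh$nodes, partition$mesh$tets)
  v_res <- sum(vols_all[keep])
  v_src <- partition$source_volume
  solid <- solid_region(mesh, partition$tag,
                        meta = c(partition$meta,
                                 list(split_plane = partition$split_plane)))
  structure(list(name = model_name(spec), spec = spec, solid = solid,
                 realized_residual_volume = v_res,
                 realized_residual_fraction = v_res / v_src,
                 removed_volume = v_src - v_res,
                 source_volume = v_src,
                 split_plane = partition$split_plane,
                 boundaries = partition$boundaries,
                 rings_removed = c(anterior = na, posterior = np),
                 smoothing_applied = FALSE),
            class = "resection_model")
}

#' @export
print.resection_model <- function(x, ...) {
  cat(sprintf("resection_model %s: residual %.1f mm^3 (%.1f%% of source)%s\n",
              x$name, x$realized_residual_volume,
              100 * x$realized_residual_fraction,
              if (x$smoothing_applied) ", smoothed" else ""))
  invisible(x)
}

#' Minimum residual rim width of a resection model
#'
#' Plan-view radial width of the residual meniscus, minimized over direction;
#' reported (not asserted) for the smallest models.
#'
#' @param model a `resection_model`.
#' @return width in mm.
#' @export
residual_rim_width <- function(model) {
  mesh <- model$solid$mesh
  rho <- mesh$fields[, "rho"]
  theta <- mesh$fields[, "theta"]
  semi <- model$solid$meta$semi_axes
  bins <- cut(theta, breaks = seq(0, 2 * pi, length.out = 37), include.lowest = TRUE)
  wmin <- Inf
  for (b in levels(bins)) {
    i <- bins == b
    if (!any(i)) next
    r_ext <- range(rho[i])
    th_mid <- mean(theta[i])
    r_dir <- sqrt((semi[1L] * cos(th_mid))^2 + (semi[2L] * sin(th_mid))^2)
    wmin <- min(wmin, (r_ext[2L] - r_ext[1L]) * r_dir)
  }
  wmin
}

# radial parameter of the deeper of the two cut walls
.deep_cut_rho <- function(model) {
  nring <- length(model$boundaries) + 1L
  k_deep <- max(model$rings_removed)
  if (k_deep == 0L) return(min(model$solid$mesh$fields[, "rho"]))
  sort(model$boundaries, decreasing = TRUE)[nring - k_deep]
}

#' Junction crease angle of a resection model
#'
#' Maximum dihedral-angle discontinuity over the inner-wall surface near the
#' anterior-posterior split plane; used to quantify the step left by unequal
#' resection and its reduction by [smooth_junction()].
#'
#' @param model a `resection_model`.
#' @param band_width band around the split plane to inspect, mm.
#' @return angle in radians.
#' @export
junction_crease <- function(model, band_width = 3) {
  rho <- model$solid$mesh$fields[, "rho"]
  max_crease_angle(model$solid, model$split_plane, band_width,
                   .deep_cut_rho(model) + 0.05 * diff(range(rho)))
}

# maximum crease (dihedral deviation from flatness) over boundary-surface
# edges whose adjacent triangle centroids lie within `band` of the split
# plane and on the inner wall (rho below `rho_max`)
max_crease_angle <- function(solid, y0, band, rho_max) {
  surf <- boundary_surface(solid$mesh, label = solid$tag)
  # map surface vertices back: boundary_surface compacts, so recompute from mesh
  mesh <- solid$mesh
  faces <- tet_faces(mesh$tets)
  key <- face_key(faces)
  cnt <- table(key)
  bf <- faces[cnt[key] == 1L, , drop = FALSE]
  nrm <- triangle_normals(surface_mesh(mesh$nodes, bf))
  ctr <- (mesh$nodes[bf[, 1L], , drop = FALSE] +
          mesh$nodes[bf[, 2L], , drop = FALSE] +
          mesh$nodes[bf[, 3L], , drop = FALSE]) / 3
  rho_f <- (mesh$fields[bf[, 1L], "rho"] + mesh$fields[bf[, 2L], "rho"] +
            mesh$fields[bf[, 3L], "rho"]) / 3
  sel <- abs(ctr[, 2L] - y0) < band & rho_f < rho_max
  if (sum(sel) < 2L) return(0)
  bf <- bf[sel, , drop = FALSE]
  nrm <- nrm[sel, , drop = FALSE]
  cy <- ctr[sel, 2L] - y0
  edges <- rbind(cbind(bf[, 1L], bf[, 2L], seq_len(nrow(bf))),
                 cbind(bf[, 2L], bf[, 3L], seq_len(nrow(bf))),
                 cbind(bf[, 3L], bf[, 1L], seq_len(nrow(bf))))
  ekey <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  ang_max <- 0
  for (k in unique(ekey[duplicated(ekey)])) {
    tris <- edges[ekey == k, 3L]
    if (length(tris) != 2L) next
    # only wall-like face pairs straddling the split plane measure the AP
    # step (top/bottom wedge faces are the meniscus profile, not the step)
    if (cy[tris[1L]] * cy[tris[2L]] > 0) next
    if (abs(nrm[tris[1L], 3L]) > 0.7 || abs(nrm[tris[2L], 3L]) > 0.7) next
    cosang <- sum(nrm[tris[1L], ] * nrm[tris[2L], ])
    ang <- acos(pmin(pmax(cosang, -1), 1))
    ang_max <- max(ang_max, ang)
  }
  ang_max
}

#' Smooth the anterior-posterior junction of an unequally resected model
#'
#' Blends the step discontinuity at the split plane by a constrained radial
#' relocation of the inner-wall node columns: the wall radius follows a
#' smoothstep ramp between the anterior and posterior cut radii over a band
#' around the plane, and each radial node column is rescaled accordingly
#' (element quality and watertightness are preserved by construction). The
#' operation is abandoned if it would invert elements or drift the volume by
#' more than 1 %.
#'
#' @param model a `resection_model`.
#' @param band_width blending band width in mm (default 3).
#' @param iterations unused, kept for interface stability.
#' @return the smoothed `resection_model` (`smoothing_applied` = TRUE); equal
#'   anterior/posterior models and `band_width = 0` return the input.
#' @export
smooth_junction <- function(model, band_width = 3, iterations = NULL) {
  stopifnot(inherits(model, "resection_model"))
  if (band_width <= 0) return(model)
  if (model$rings_removed["anterior"] == model$rings_removed["posterior"])
    return(model)
  meta <- model$solid$meta
  if (is.null(meta$config))
    stop("smooth_junction: model lacks its construction metadata")
  cfg <- meta$config
  mesh <- model$solid$mesh
  v_before <- sum(tet_volumes(mesh$nodes, mesh$tets))
  rho <- mesh$fields[, "rho"]
  theta <- mesh$fields[, "theta"]
  zeta <- mesh$fields[, "zeta"]
  nring <- length(model$boundaries) + 1L
  wall_radius <- function(k) {
    if (k == 0L) min(rho) else sort(model$boundaries, decreasing = TRUE)[nring - k]
  }
  u_a <- wall_radius(model$rings_removed[["anterior"]])
  u_p <- wall_radius(model$rings_removed[["posterior"]])
  semi <- meta$semi_axes
  ctr <- meta$centre
  u_mid <- (u_a + u_p) / 2
  # smooth ramp of the inner-wall radius across the split plane: parameter is
  # the signed anterior distance of the wall point from the plane, scaled by
  # the band width
  sstep <- function(t) {
    t <- pmin(pmax(t, 0), 1)
    t * t * (3 - 2 * t)
  }
  y_wall <- semi[2L] * u_mid * sin(theta)        # signed, + = anterior
  Hn <- sstep((y_wall + band_width) / (2 * band_width))
  u_tgt_n <- u_p + (u_a - u_p) * Hn
  # per-column source wall radius (columns = distinct theta values)
  col <- match(round(theta, 9), unique(round(theta, 9)))
  u_src_n <- stats::ave(rho, col, FUN = min)
  scale <- (1 - u_tgt_n) / pmax(1 - u_src_n, 1e-12)
  new_rho <- u_tgt_n + (rho - u_src_n) * scale
  moved <- abs(new_rho - rho) > 1e-12
  if (any(moved)) {
    cf <- .condyle_funs(cfg, meta$side)
    tc <- cfg$cartilage_thickness
    h_per <- cfg$meniscus_peripheral_height
    xg <- ctr[1L] + semi[1L] * new_rho * cos(theta)
    yg <- ctr[2L] + semi[2L] * new_rho * sin(theta)
    zb <- rep(tc, length(xg))
    zt <- pmin(cf$z_outer(xg, yg), tc + h_per)
    zg <- zb + zeta * (zt - zb)
    nodes <- mesh$nodes
    nodes[moved, 1L] <- cfg$lateral_sign * xg[moved]
    nodes[moved, 2L] <- yg[moved]
    nodes[moved, 3L] <- zg[moved]
    vols <- tet_volumes(nodes, mesh$tets)
    if (any(vols <= 0)) {
      warning("smooth_junction: remap would invert elements; returning unsmoothed model")
      return(model)
    }
    v_after <- sum(vols)
    if (abs(v_after - v_before) / v_before > 0.01) {
      warning("smooth_junction: volume drift above 1%; returning unsmoothed model")
      return(model)
    }
    mesh$nodes <- nodes
    mesh$fields[, "rho"] <- new_rho
  } else {
    v_after <- v_before
  }
  solid <- solid_region(mesh, model$solid$tag, meta = meta)
  model$solid <- solid
  model$realized_residual_volume <- v_after
  model$realized_residual_fraction <- v_after / model$source_volume
  model$smoothing_applied <- TRUE
  model
}
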