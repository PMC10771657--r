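# Parametric synthetic tibiofemoral joint at full extension.
#
# Coordinate convention: x = medial -> lateral, y = posterior -> anterior,
# z = inferior -> superior; origin at the tibial plateau centroid; units mm,
# MPa, N. The geometry is an idealized stand-in for a segmented knee: rigid
# femur/tibia surfaces, bi-radius (paraboloidal) femoral condyles coated with
# cartilage, flat-topped tibial cartilage plates, a discoid lateral meniscus
# covering the lateral plateau and an annular (C-shaped) medial meniscus.
# The femoral cartilage carries a linear anterior-posterior thickness
# gradient (`cartilage_ap_gradient`): thinner, hence stiffer in compression,
# anteriorly. This reproduces the anterior-dominant tibiofemoral contact of
# the extended knee and is what makes anterior and posterior resections
# biomechanically distinct, while the articulating surfaces and the meniscus
# remain exactly AP-symmetric (so equal-volume resection pairs really have
# equal volumes).

#' Geometry configuration for the synthetic knee
#'
#' All lengths in mm. Defaults describe an idealized adult knee; none are
#' patient measurements.
#'
#' @param condyle_radius_sagittal condyle radius of curvature in the sagittal
#'   (y-z) plane.
#' @param condyle_radius_frontal condyle radius in the frontal (x-z) plane.
#' @param condyle_spacing medial-lateral distance between compartment centres.
#' @param plateau_halfwidths list with `lateral` and `medial`, each c(ml, ap)
#'   elliptic semi-axes of the tibial cartilage plates.
#' @param cartilage_thickness uniform cartilage thickness.
#' @param meniscus_peripheral_height meniscus wedge height at the outer rim.
#' @param meniscus_inner_height meniscus thickness under the condyle apex.
#' @param discoid_coverage fraction of the lateral plateau area covered by the
#'   discoid meniscus, in (0.9, 1].
#' @param medial_meniscus_inner_rim_ratio inner rim radius ratio of the medial
#'   meniscus (0 gives a solid disc).
#' @param condyle_ap_offset anterior offset of the condyle contact centre from
#'   the plateau centre (default 0: offsetting the centre makes the meniscus
#'   AP-asymmetric, which breaks the equal-volume property of resection
#'   pairs; the anterior contact bias is carried by the thickness gradient
#'   instead).
#' @param cartilage_ap_gradient dimensionless linear anterior-posterior
#'   femoral cartilage thickness gradient: thickness varies by this fraction
#'   of `cartilage_thickness` per AP half-width, thinner (stiffer)
#'   anteriorly.
#' @param lateral_sign +1 places the lateral compartment at +x, -1 mirrors the
#'   joint in the medial-lateral axis.
#' @param ligament_attachment_points labelled 3D attachment coordinates; NULL
#'   computes anatomically-placed defaults on the bone surfaces.
#' @param ligament_fiber_counts named integer vector of fibers per ligament.
#' @param mesh list of meshing controls: `edge_length` (target element edge,
#'   mm, cartilage and menisci), `bone_facet` (rigid surface facet size, mm).
#' @param random_seed integer seed stored with the config; the construction
#'   is fully deterministic, the seed only tags the configuration.
#' @return object of class `knee_config`.
#' @export
knee_config <- function(condyle_radius_sagittal = 32,
                        condyle_radius_frontal = 24,
                        condyle_spacing = 36,
                        plateau_halfwidths = list(lateral = c(ml = 15, ap = 17),
                                                  medial = c(ml = 15, ap = 17)),
                        cartilage_thickness = 2,
                        meniscus_peripheral_height = 7,
                        meniscus_inner_height = 2,
                        discoid_coverage = 0.95,
                        medial_meniscus_inner_rim_ratio = 0.55,
                        condyle_ap_offset = 0,
                        cartilage_ap_gradient = 0.35,
                        lateral_sign = 1,
                        ligament_attachment_points = NULL,
                        ligament_fiber_counts = c(ACL = 3L, PCL = 3L,
                                                  MCL = 3L, LCL = 3L, PQ = 2L),
                        mesh = list(edge_length = 1.5, bone_facet = 2.0),
                        random_seed = 1L) {
  cfg <- list(condyle_radius_sagittal = condyle_radius_sagittal,
              condyle_radius_frontal = condyle_radius_frontal,
              condyle_spacing = condyle_spacing,
              plateau_halfwidths = plateau_halfwidths,
              cartilage_thickness = cartilage_thickness,
              meniscus_peripheral_height = meniscus_peripheral_height,
              meniscus_inner_height = meniscus_inner_height,
              discoid_coverage = discoid_coverage,
              medial_meniscus_inner_rim_ratio = medial_meniscus_inner_rim_ratio,
              condyle_ap_offset = condyle_ap_offset,
              cartilage_ap_gradient = cartilage_ap_gradient,
              lateral_sign = lateral_sign,
              ligament_attachment_points = ligament_attachment_points,
              ligament_fiber_counts = ligament_fiber_counts,
              mesh = mesh,
              random_seed = as.integer(random_seed))
  class(cfg) <- "knee_config"
  validate_knee_config(cfg)
  cfg
}

#' Validate a knee configuration
#' @param cfg a `knee_config`.
#' @return the config, invisibly; stops with the offending field on error.
#' @export
validate_knee_config <- function(cfg) {
  pos <- c("condyle_radius_sagittal", "condyle_radius_frontal",
           "condyle_spacing", "cartilage_thickness",
           "meniscus_peripheral_height", "meniscus_inner_height")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(sprintf("knee_config: field '%s' must be a positive length", f))
  }
  for (side in c("lateral", "medial")) {
    hw <- cfg$plateau_halfwidths[[side]]
    if (is.null(hw) || length(hw) != 2L || any(hw <= 0))
      stop(sprintf("knee_config: field 'plateau_halfwidths$%s' must be two positive lengths", side))
  }
  if (!(cfg$discoid_coverage > 0.9 && cfg$discoid_coverage <= 1.0))
    stop("knee_config: field 'discoid_coverage' must lie in (0.9, 1]")
  if (cfg$medial_meniscus_inner_rim_ratio < 0 ||
      cfg$medial_meniscus_inner_rim_ratio >= 1)
    stop("knee_config: field 'medial_meniscus_inner_rim_ratio' must lie in [0, 1)")
  if (cfg$cartilage_thickness >= cfg$condyle_radius_frontal)
    stop("knee_config: field 'cartilage_thickness' must be smaller than 'condyle_radius_frontal'")
  if (cfg$meniscus_inner_height > cfg$meniscus_peripheral_height)
    stop("knee_config: field 'meniscus_inner_height' must not exceed 'meniscus_peripheral_height'")
  if (!cfg$lateral_sign %in% c(-1, 1))
    stop("knee_config: field 'lateral_sign' must be +1 or -1")
  invisible(cfg)
}

#' @export
print.knee_config <- function(x, ...) {
  cat("knee_config (mm): condyles Rs =", x$condyle_radius_sagittal,
      "Rf =", x$condyle_radius_frontal,
      "| spacing", x$condyle_spacing,
      "| cartilage", x$cartilage_thickness,
      "| meniscus", x$meniscus_inner_height, "-", x$meniscus_peripheral_height,
      "| discoid coverage", x$discoid_coverage, "\n")
  invisible(x)
}

# compartment centre in the canonical (+x lateral) frame
.comp_centre <- function(cfg, side) {
  s <- if (side == "lateral") cfg$condyle_spacing / 2 else -cfg$condyle_spacing / 2
  c(s, 0)
}

# Femoral condyle surfaces in the canonical frame. The articulating
# (cartilage outer) surface is the bi-radius paraboloid; the bone surface
# lies a cartilage thickness above it along the local normal. The thickness
# carries a linear anterior-posterior gradient (thinner, stiffer anteriorly),
# which is what concentrates contact in the anterior compartment while the
# articulating surfaces and the meniscus stay exactly AP-symmetric.
.condyle_funs <- function(cfg, side) {
  ctr <- .comp_centre(cfg, side)
  xc <- ctr[1L]
  yc <- cfg$condyle_ap_offset
  Rf <- cfg$condyle_radius_frontal
  Rs <- cfg$condyle_radius_sagittal
  tc <- cfg$cartilage_thickness
  gam <- cfg$cartilage_ap_gradient
  ap <- cfg$plateau_halfwidths[[side]][2L]
  z_apex <- cfg$cartilage_thickness + cfg$meniscus_inner_height
  z_outer <- function(x, y) z_apex + (x - xc)^2 / (2 * Rf) + (y - yc)^2 / (2 * Rs)
  thickness <- function(x, y) pmax(0.3 * tc, tc * (1 - gam * (y - yc) / ap))
  z_bone <- function(x, y) {
    gx <- (x - xc) / Rf
    gy <- (y - yc) / Rs
    z_outer(x, y) + thickness(x, y) * sqrt(1 + gx^2 + gy^2)
  }
  list(z_bone = z_bone, z_outer = z_outer, thickness = thickness,
       centre = c(xc, yc))
}

# mirror the x coordinate of a tet mesh when lateral_sign = -1
.apply_side_sign <- function(mesh, sign) {
  if (sign == 1) return(mesh)
  mesh$nodes[, 1L] <- -mesh$nodes[, 1L]
  mesh$tets <- fix_tet_orientation(mesh$nodes, mesh$tets)
  mesh
}

#' Wrap a tet mesh as a tagged solid region
#' @param mesh single-region `tet_mesh`.
#' @param tag region tag.
#' @param meta optional list of construction metadata.
#' @return object of class `solid_region` with watertight `boundary`.
#' @export
solid_region <- function(mesh, tag, meta = list()) {
  boundary <- boundary_surface(mesh, label = tag)
  structure(list(mesh = mesh, boundary = boundary, tag = tag,
                 volume = sum(tet_volumes(mesh$nodes, mesh$tets)),
                 meta = meta),
            class = "solid_region")
}

#' @export
print.solid_region <- function(x, ...) {
  cat(sprintf("solid_region '%s': %d tets, volume %.2f mm^3\n",
              x$tag, nrow(x$mesh$tets), x$volume))
  invisible(x)
}

# meniscus divisions from target edge length; the angular count is forced
# even so the anterior-posterior symmetry plane (y = 0 through the plateau
# centre) is a mesh plane and needs no element cutting
.meniscus_divisions <- function(cfg, semi, rho_in) {
  h <- cfg$mesh$edge_length
  per <- pi * (3 * (semi[1L] + semi[2L]) -
               sqrt((3 * semi[1L] + semi[2L]) * (semi[1L] + 3 * semi[2L])))
  n_theta <- max(16L, 2L * as.integer(round(per / h / 2)))
  rad_ext <- (1 - rho_in) * mean(semi)
  n_rho <- max(3L, as.integer(round(rad_ext / h)))
  n_zeta <- max(2L, as.integer(round(cfg$meniscus_peripheral_height / h)))
  list(n_rho = n_rho, n_theta = n_theta, n_zeta = n_zeta)
}

.build_meniscus <- function(cfg, side, rho_in, tag, rho_values = NULL) {
  hw <- cfg$plateau_halfwidths[[side]]
  ctr <- .comp_centre(cfg, side)
  cf <- .condyle_funs(cfg, side)
  tc <- cfg$cartilage_thickness
  h_per <- cfg$meniscus_peripheral_height
  z_bot <- function(x, y) rep(tc, length(x))
  z_top <- function(x, y) pmin(cf$z_outer(x, y), tc + h_per)
  dv <- .meniscus_divisions(cfg, hw, rho_in)
  m <- annulus_mesh(ctr, hw, rho_in, z_bot, z_top,
                    n_rho = dv$n_rho, n_theta = dv$n_theta, n_zeta = dv$n_zeta,
                    region = tag, rho_values = rho_values)
  m <- .apply_side_sign(m, cfg$lateral_sign)
  solid_region(m, tag,
               meta = list(centre = ctr, semi_axes = hw, rho_in = rho_in,
                           side = side, lateral_sign = cfg$lateral_sign,
                           config = cfg, tag = tag))
}

#' Build the discoid lateral meniscus
#'
#' A watertight wedge-profiled disc: thickness equals
#' `meniscus_peripheral_height` at the outer rim and tapers inward; the
#' superior surface conforms to the lateral femoral cartilage within the
#' condylar dish, the inferior surface lies on the lateral tibial cartilage.
#' The projected area covers `discoid_coverage` of the lateral plateau; the
#' central hole vanishes at coverage 1 (solid disc).
#'
#' @param config a `knee_config`.
#' @param side compartment to build on ("lateral" default; "medial" builds
#'   the same discoid construction on the medial plateau, used for limit-case
#'   comparisons).
#' @return a `solid_region` tagged `meniscus_lateral` (or `_medial`).
#' @export
build_discoid_meniscus <- function(config, side = "lateral") {
  validate_knee_config(config)
  if (config$meniscus_inner_height <= 0)
    stop("build_discoid_meniscus: taper parameters produce non-positive thickness")
  rho_in <- sqrt(1 - config$discoid_coverage)
  tag <- paste0("meniscus_", side)
  .build_meniscus(config, side, rho_in, tag)
}

#' Build the medial (C-shaped) meniscus
#'
#' Annulus with inner rim opening governed by
#' `medial_meniscus_inner_rim_ratio`; ratio 0 gives a solid disc. Same wedge
#' profile and conforming surfaces as the discoid construction.
#'
#' @param config a `knee_config`.
#' @return a `solid_region` tagged `meniscus_medial`.
#' @export
build_medial_meniscus <- function(config) {
  validate_knee_config(config)
  .build_meniscus(config, "medial", config$medial_meniscus_inner_rim_ratio,
                  "meniscus_medial")
}

.build_cartilage <- function(cfg, side, which) {
  hw <- cfg$plateau_halfwidths[[side]]
  ctr <- .comp_centre(cfg, side)
  tc <- cfg$cartilage_thickness
  h <- cfg$mesh$edge_length
  if (which == "tibial") {
    semi <- hw
    z_bot <- function(x, y) rep(0, length(x))
    z_top <- function(x, y) rep(tc, length(x))
    centre <- ctr
    tag <- paste0("tibial_cartilage_", side)
  } else {
    cf <- .condyle_funs(cfg, side)
    semi <- hw * 0.9            # femoral cartilage footprint slightly inset
    z_bot <- cf$z_outer
    z_top <- cf$z_bone
    centre <- cf$centre
    tag <- paste0("femoral_cartilage_", side)
  }
  per <- pi * (3 * (semi[1L] + semi[2L]) -
               sqrt((3 * semi[1L] + semi[2L]) * (semi[1L] + 3 * semi[2L])))
  n_theta <- max(16L, as.integer(round(per / h)))
  n_rho <- max(3L, as.integer(round(mean(semi) / h)))
  n_zeta <- max(2L, as.integer(round(tc / h)))
  m <- annulus_mesh(centre, semi, 0, z_bot, z_top,
                    n_rho = n_rho, n_theta = n_theta, n_zeta = n_zeta,
                    region = tag)
  m <- .apply_side_sign(m, cfg$lateral_sign)
  solid_region(m, tag,
               meta = list(centre = centre, semi_axes = semi, side = side,
                           which = which, lateral_sign = cfg$lateral_sign))
}

# triangulated graph surface over an elliptic footprint (rigid bone patch)
.graph_patch <- function(centre, semi, zfun, facet, label, sign = 1) {
  per <- 2 * pi * mean(semi)
  n_theta <- max(12L, as.integer(round(per / facet)))
  n_rho <- max(3L, as.integer(round(mean(semi) / facet)))
  rho <- seq(0, 1, length.out = n_rho + 1L)[-1L]
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  nid <- function(i, j) ((j - 1L) %% n_theta) * n_rho + i
  rho_g <- rep(rho, times = n_theta)
  th_g <- rep(th, each = n_rho)
  xg <- centre[1L] + semi[1L] * rho_g * cos(th_g)
  yg <- centre[2L] + semi[2L] * rho_g * sin(th_g)
  xg <- c(xg, centre[1L]); yg <- c(yg, centre[2L])
  ax <- n_rho * n_theta + 1L
  zg <- zfun(xg, yg)
  tris <- list()
  for (j in seq_len(n_theta)) {
    tris[[length(tris) + 1L]] <- c(ax, nid(1L, j), nid(1L, j + 1L))
    for (i in seq_len(n_rho - 1L)) {
      tris[[length(tris) + 1L]] <- c(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L))
      tris[[length(tris) + 1L]] <- c(nid(i, j), nid(i + 1L, j + 1L), nid(i, j + 1L))
    }
  }
  v <- cbind(sign * xg, yg, zg)
  surface_mesh(v, do.call(rbind, tris), label = label)
}

#' Default ligament attachment coordinates
#'
#' Computed on the analytic bone surfaces of the configuration: cruciates in
#' the intercondylar region, collaterals at the compartment peripheries,
#' patellar/quadriceps fibers from the anterior condyle margins to a fixed
#' anterior virtual point (the patella is not modelled as a body).
#'
#' @param config a `knee_config`.
#' @return named list of lists with `femur` and `tibia` 3D points (canonical
#'   +x = lateral frame; `lateral_sign` is applied by `build_knee_geometry`).
#' @export
default_ligament_attachments <- function(config) {
  lat <- .condyle_funs(config, "lateral")
  med <- .condyle_funs(config, "medial")
  s2 <- config$condyle_spacing / 2
  ml_l <- config$plateau_halfwidths$lateral[1L]
  ml_m <- config$plateau_halfwidths$medial[1L]
  on_lat <- function(x, y) c(x, y, lat$z_bone(x, y))
  on_med <- function(x, y) c(x, y, med$z_bone(x, y))
  list(
    ACL = list(femur = on_lat(s2 - 12, config$condyle_ap_offset - 8),
               tibia = c(0, 8, 0)),
    PCL = list(femur = on_med(-(s2 - 12), config$condyle_ap_offset + 2),
               tibia = c(0, -12, 0)),
    MCL = list(femur = on_med(-(s2 + ml_m * 0.7), 0),
               tibia = c(-(s2 + ml_m * 0.7), 0, 0)),
    LCL = list(femur = on_lat(s2 + ml_l * 0.7, 0),
               tibia = c(s2 + ml_l * 0.7, -2, 0)),
    PQ = list(femur = on_lat(s2 * 0.4, config$condyle_ap_offset + 12),
              tibia = c(0, 30, 10))   # fixed virtual point (patella proxy)
  )
}

.build_ligaments <- function(cfg) {
  atts <- cfg$ligament_attachment_points
  if (is.null(atts)) atts <- default_ligament_attachments(cfg)
  total_area <- c(ACL = 40, PCL = 40, MCL = 25, LCL = 25, PQ = 60)
  mat_ref <- c(ACL = "acl_neo_hookean", PCL = "pcl_neo_hookean",
               MCL = "ligament_linear", LCL = "ligament_linear",
               PQ = "ligament_linear")
  out <- list()
  for (nm in names(atts)) {
    nf <- cfg$ligament_fiber_counts[[nm]]
    if (is.null(nf) || is.na(nf)) nf <- 3L
    fem <- atts[[nm]]$femur
    tib <- atts[[nm]]$tibia
    # deterministic small spread of fiber endpoints about the centre
    offs <- seq(-1, 1, length.out = max(nf, 2L))[seq_len(nf)]
    fibers <- lapply(offs, function(o) {
      d <- c(0, o, 0)     # spread along y
      rbind(femur = fem + d, tibia = tib + d)
    })
    fibers <- lapply(fibers, function(fb) {
      fb[, 1L] <- cfg$lateral_sign * fb[, 1L]
      fb
    })
    ta <- if (nm %in% names(total_area)) total_area[[nm]] else 30
    out[[nm]] <- structure(list(
      name = nm,
      fibers = fibers,
      cross_section_area = ta / nf,
      material_ref = mat_ref[[nm]],
      rest_lengths = vapply(fibers, function(fb)
        sqrt(sum((fb[1L, ] - fb[2L, ])^2)), 0)),
      class = "ligament_element")
  }
  out
}

#' Build the full synthetic knee geometry
#'
#' Assembles rigid femur and tibia surfaces, four cartilage solids, the
#' discoid lateral and annular medial menisci and the ligament fiber sets, at
#' full extension. All solids are watertight and mutually non-penetrating;
#' the menisci conform to the cartilage layers (zero initial gap inside the
#' condylar dish).
#'
#' @param config a `knee_config`.
#' @return object of class `knee_geometry` with elements `config`,
#'   `femur_surface`, `tibia_surface`, `solids` (named list of 6
#'   `solid_region`s), `ligaments`, `axes`.
#' @export
build_knee_geometry <- function(config) {
  validate_knee_config(config)
  solids <- list(
    femoral_cartilage_lateral = .build_cartilage(config, "lateral", "femoral"),
    femoral_cartilage_medial = .build_cartilage(config, "medial", "femoral"),
    tibial_cartilage_lateral = .build_cartilage(config, "lateral", "tibial"),
    tibial_cartilage_medial = .build_cartilage(config, "medial", "tibial"),
    meniscus_lateral = build_discoid_meniscus(config),
    meniscus_medial = build_medial_meniscus(config)
  )
  for (s in solids) {
    if (s$volume <= 0)
      stop("build_knee_geometry: generated solid has non-positive volume: ", s$tag)
  }
  # interpenetration audit: meniscus top must not rise above the femoral
  # cartilage outer surface, menisci/cartilage plates share flat interfaces
  for (side in c("lateral", "medial")) {
    men <- solids[[paste0("meniscus_", side)]]
    cf <- .condyle_funs(config, side)
    nd <- men$mesh$nodes
    top <- men$mesh$fields[, "zeta"] > 1 - 1e-9
    pen <- men$mesh$nodes[top, 3L] -
           cf$z_outer(config$lateral_sign * nd[top, 1L], nd[top, 2L])
    if (any(pen > 0.01))
      stop("build_knee_geometry: meniscus interpenetrates femoral cartilage on ",
           side, " side (max ", signif(max(pen), 3), " mm)")
  }
  facet <- config$mesh$bone_facet
  lat <- .condyle_funs(config, "lateral")
  med <- .condyle_funs(config, "medial")
  femur_surface <- local({
    a <- .graph_patch(lat$centre, config$plateau_halfwidths$lateral,
                      lat$z_bone, facet, "femur", sign = config$lateral_sign)
    b <- .graph_patch(med$centre, config$plateau_halfwidths$medial,
                      med$z_bone, facet, "femur", sign = config$lateral_sign)
    surface_mesh(rbind(a$vertices, b$vertices),
                 rbind(a$triangles, b$triangles + nrow(a$vertices)),
                 label = "femur")
  })
  tibia_surface <- local({
    ext <- config$condyle_spacing / 2 +
           max(config$plateau_halfwidths$lateral[1L],
               config$plateau_halfwidths$medial[1L]) + 6
    xs <- seq(-ext, ext, by = facet)
    ys <- seq(-22, 32, by = facet)
    nx <- length(xs); ny <- length(ys)
    nid <- function(i, j) (j - 1L) * nx + i
    v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
    tris <- list()
    for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
      tris[[length(tris) + 1L]] <- c(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L))
      tris[[length(tris) + 1L]] <- c(nid(i, j), nid(i + 1L, j + 1L), nid(i, j + 1L))
    }
    surface_mesh(v, do.call(rbind, tris), label = "tibia_fibula")
  })
  structure(list(config = config,
                 femur_surface = femur_surface,
                 tibia_surface = tibia_surface,
                 solids = solids,
                 ligaments = .build_ligaments(config),
                 axes = list(x = "medial->lateral", y = "posterior->anterior",
                             z = "inferior->superior",
                             origin = "tibial plateau centroid",
                             units = c(length = "mm", stress = "MPa",
                                       force = "N"))),
            class = "knee_geometry")
}

#' @export
print.knee_geometry <- function(x, ...) {
  cat("knee_geometry: 6 solids, ", length(x$ligaments), " ligaments\n", sep = "")
  for (s in x$solids) print(s)
  invisible(x)
}

#' Initial meniscus-cartilage clearance report
#'
#' Measures the vertical gap between each meniscus superior surface and the
#' overlying femoral cartilage within the conforming condylar dish, and the
#' gap between the meniscus inferior surface and the tibial cartilage plate.
#'
#' @param geometry a `knee_geometry`.
#' @return data.frame with per-meniscus fraction of facing nodes with gap in
#'   [0, 0.05] mm and the maximum gap.
#' @export
geometry_clearance <- function(geometry) {
  cfg <- geometry$config
  out <- list()
  for (side in c("lateral", "medial")) {
    men <- geometry$solids[[paste0("meniscus_", side)]]
    cf <- .condyle_funs(cfg, side)
    nd <- men$mesh$nodes
    zeta <- men$mesh$fields[, "zeta"]
    top <- zeta > 1 - 1e-9
    xg <- cfg$lateral_sign * nd[top, 1L]
    zo <- cf$z_outer(xg, nd[top, 2L])
    # facing (dish) region: where the conforming surface lies below the
    # peripheral wedge cap
    dish <- zo < cfg$cartilage_thickness + cfg$meniscus_peripheral_height - 1e-9
    gap_top <- zo[dish] - nd[top, 3L][dish]
    bot <- zeta < 1e-9
    gap_bot <- nd[bot, 3L] - cfg$cartilage_thickness
    out[[side]] <- data.frame(
      meniscus = side,
      frac_top_within = mean(gap_top >= -1e-9 & gap_top <= 0.05),
      frac_bot_within = mean(abs(gap_bot) <= 0.05),
      max_gap = max(c(gap_top, abs(gap_bot))))
  }
  do.call(rbind, out)
}
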