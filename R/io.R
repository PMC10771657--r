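# File interchange: STL surface export/import (ASCII for portability),
# Gmsh MSH v4.1 volume export, geometry-config JSON round trip and the
# resection-family manifest.

#' Write a surface mesh to an ASCII STL file
#' @param surface a `surface_mesh`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_stl <- function(surface, path) {
  n <- triangle_normals(surface)
  v <- surface$vertices
  tr <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", surface$label), con)
  for (f in seq_len(nrow(tr))) {
    writeLines(c(sprintf("  facet normal %.9e %.9e %.9e", n[f, 1L], n[f, 2L], n[f, 3L]),
                 "    outer loop",
                 sprintf("      vertex %.9e %.9e %.9e",
                         v[tr[f, ], 1L], v[tr[f, ], 2L], v[tr[f, ], 3L]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", surface$label), con)
  invisible(path)
}

#' Read an ASCII STL file
#' @param path STL file.
#' @param label label for the resulting surface.
#' @param merge_tol vertices closer than this are merged (mm).
#' @return a `surface_mesh`.
#' @export
read_stl <- function(path, label = basename(path), merge_tol = 1e-9) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (nrow(nums) %% 3L != 0L) stop("read_stl: malformed STL (vertex count)")
  key <- apply(round(nums / max(merge_tol, 1e-12)), 1L, paste, collapse = "/")
  ids <- match(key, unique(key))
  verts <- nums[!duplicated(key), , drop = FALSE]
  tris <- matrix(ids, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, tris, label = label)
}

#' Write a tet mesh to a Gmsh MSH v4.1 (ASCII) file
#' @param mesh a `tet_mesh`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("$MeshFormat", "4.1 0 8", "$EndMeshFormat"), con)
  writeLines(c("$Nodes", sprintf("1 %d 1 %d", n, n),
               sprintf("3 1 0 %d", n),
               as.character(seq_len(n)),
               sprintf("%.10g %.10g %.10g",
                       mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
               "$EndNodes"), con)
  writeLines(c("$Elements", sprintf("1 %d 1 %d", m, m),
               sprintf("3 1 4 %d", m),
               sprintf("%d %d %d %d %d", seq_len(m),
                       mesh$tets[, 1L], mesh$tets[, 2L],
                       mesh$tets[, 3L], mesh$tets[, 4L]),
               "$EndElements"), con)
  invisible(path)
}

#' Serialize a knee configuration to JSON
#' @param config a `knee_config`.
#' @param path output file (NULL returns the JSON string).
#' @return the path, or the JSON string when `path` is NULL.
#' @export
write_knee_config <- function(config, path = NULL) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Load a knee configuration from JSON
#' @param path JSON file from [write_knee_config()].
#' @return a validated `knee_config`.
#' @export
read_knee_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$plateau_halfwidths <- lapply(x$plateau_halfwidths, function(v)
    stats::setNames(as.numeric(v), c("ml", "ap")))
  x$ligament_fiber_counts <- unlist(x$ligament_fiber_counts)
  do.call(knee_config, x)
}

#' Resection-family manifest table
#'
#' One row per model of the family resected from a partition: canonical
#' name, anterior/posterior fractions, realized residual volume and
#' fraction.
#'
#' @param partition an AP-split `meniscus_partition`.
#' @param smooth apply junction smoothing to unequal models.
#' @param path optional CSV output path.
#' @return data.frame (written to `path` when given).
#' @export
family_manifest <- function(partition, smooth = TRUE, path = NULL) {
  fam <- enumerate_family()
  rows <- lapply(fam, function(sp) {
    m <- resect(partition, sp)
    if (smooth) m <- smooth_junction(m)
    data.frame(name = m$name,
               anterior_fraction = sp$anterior_fraction,
               posterior_fraction = sp$posterior_fraction,
               residual_volume_mm3 = m$realized_residual_volume,
               residual_fraction = m$realized_residual_fraction,
               smoothed = m$smoothing_applied)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Export every surface of a knee geometry
#'
#' Writes the rigid bone surfaces and each solid boundary as ASCII STL and
#' each solid volume mesh as Gmsh MSH v4.1.
#'
#' @param geometry a `knee_geometry`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
export_geometry <- function(geometry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "femur.stl")
  write_stl(geometry$femur_surface, f); files <- c(files, f)
  f <- file.path(dir, "tibia_fibula.stl")
  write_stl(geometry$tibia_surface, f); files <- c(files, f)
  for (s in geometry$solids) {
    f <- file.path(dir, paste0(s$tag, ".stl"))
    write_stl(s$boundary, f); files <- c(files, f)
    f <- file.path(dir, paste0(s$tag, ".msh"))
    write_msh(s$mesh, f); files <- c(files, f)
  }
  invisible(files)
}
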