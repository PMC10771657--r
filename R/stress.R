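# Stress recovery and the two readouts of the study: Tresca stress (stress
# intensity, sigma1 - sigma3 = twice the maximum shear stress) and minimum
# principal (compressive) stress, with per-compartment peak extraction over
# the six regions MFC, LFC, MM, LM, MTC, LTC.

#' Recover element stresses from a solution
#'
#' Element-constant TET4 stress via the material law applied to the element
#' strain; no nodal averaging.
#'
#' @param mesh a `tet_mesh`.
#' @param u nodal displacement vector (3n, mm).
#' @param materials material cards keyed by region tag.
#' @return object of class `stress_field`: m x 6 Voigt stresses (MPa) plus
#'   region tags and element centroids.
#' @export
recover_stresses <- function(mesh, u, materials) {
  eps <- element_strains(mesh, u)
  Call <- element_C(mesh, materials)
  m <- nrow(eps)
  sig <- matrix(0, m, 6L)
  for (p in 1:6) for (q in 1:6) sig[, p] <- sig[, p] + Call[, p, q] * eps[, q]
  ctr <- (mesh$nodes[mesh$tets[, 1L], , drop = FALSE] +
          mesh$nodes[mesh$tets[, 2L], , drop = FALSE] +
          mesh$nodes[mesh$tets[, 3L], , drop = FALSE] +
          mesh$nodes[mesh$tets[, 4L], , drop = FALSE]) / 4
  structure(list(stress = sig, region = mesh$region, centroid = ctr),
            class = "stress_field")
}

#' Principal stresses of symmetric stress tensors
#'
#' Closed-form (trigonometric) eigenvalues of the symmetric 3x3 tensors,
#' sorted descending; vectorized over rows of a Voigt matrix
#' (11, 22, 33, 23, 13, 12).
#'
#' @param sig numeric vector (length 6) or m x 6 matrix.
#' @return m x 3 matrix (sigma1 >= sigma2 >= sigma3), MPa.
#' @export
principal_stresses <- function(sig) {
  if (is.null(dim(sig))) sig <- matrix(sig, 1L)
  s11 <- sig[, 1L]; s22 <- sig[, 2L]; s33 <- sig[, 3L]
  s23 <- sig[, 4L]; s13 <- sig[, 5L]; s12 <- sig[, 6L]
  q <- (s11 + s22 + s33) / 3
  p2 <- (s11 - q)^2 + (s22 - q)^2 + (s33 - q)^2 + 2 * (s12^2 + s13^2 + s23^2)
  p <- sqrt(p2 / 6)
  out <- matrix(0, length(q), 3L)
  nz <- p > 1e-300
  out[!nz, ] <- q[!nz]
  if (any(nz)) {
    a11 <- (s11 - q) / p; a22 <- (s22 - q) / p; a33 <- (s33 - q) / p
    a12 <- s12 / p; a13 <- s13 / p; a23 <- s23 / p
    detB <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
            a13 * (a12 * a23 - a22 * a13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q + 2 * p * cos(phi)
    e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    e2 <- 3 * q - e1 - e3
    out[nz, 1L] <- e1[nz]; out[nz, 2L] <- e2[nz]; out[nz, 3L] <- e3[nz]
  }
  out
}

#' Tresca stress (stress intensity)
#'
#' sigma1 - sigma3, twice the maximum shear stress; the study's "shear
#' stress" readout.
#'
#' @param sig Voigt vector or matrix as in [principal_stresses()].
#' @return numeric vector, MPa.
#' @export
tresca <- function(sig) {
  pr <- principal_stresses(sig)
  pr[, 1L] - pr[, 3L]
}

#' Minimum principal stress and compressive magnitude
#'
#' @param sig Voigt vector or matrix.
#' @return data.frame with `sigma3` (signed, MPa) and `compressive`
#'   (max(0, -sigma3)).
#' @export
min_principal <- function(sig) {
  pr <- principal_stresses(sig)
  data.frame(sigma3 = pr[, 3L], compressive = pmax(0, -pr[, 3L]))
}

#' von Mises equivalent stress (used in sanity bands)
#' @param sig Voigt vector or matrix.
#' @return numeric vector, MPa.
#' @export
von_mises <- function(sig) {
  pr <- principal_stresses(sig)
  sqrt(((pr[, 1L] - pr[, 2L])^2 + (pr[, 2L] - pr[, 3L])^2 +
        (pr[, 1L] - pr[, 3L])^2) / 2)
}

# canonical compartment of a region tag + centroid x sign
.compartment <- function(region, x) {
  side <- ifelse(x >= 0, "lateral", "medial")  # +x = lateral (canonical)
  ifelse(grepl("^femoral_cartilage", region), ifelse(side == "lateral", "LFC", "MFC"),
  ifelse(grepl("^tibial_cartilage", region), ifelse(side == "lateral", "LTC", "MTC"),
  ifelse(grepl("^meniscus_lateral", region), "LM",
  ifelse(grepl("^meniscus_medial", region), "MM", NA_character_))))
}

#' Per-compartment peak stresses
#'
#' Peak Tresca and peak compressive (|minimum principal|) stress over the
#' elements of each compartment: MFC, LFC, MM, LM, MTC, LTC. Femoral and
#' tibial cartilage are split medial/lateral by the sign of the element
#' centroid x. Peaks are deterministic (ties broken by lowest element id);
#' empty compartments are recorded as NA, not zero.
#'
#' @param field a `stress_field`.
#' @param lateral_sign +1 if the lateral compartment lies at +x.
#' @return object of class `region_peaks`: data.frame with region, peak
#'   Tresca, peak compressive magnitude, signed minimum principal, and the
#'   element id of each peak.
#' @export
region_peaks <- function(field, lateral_sign = 1) {
  tr <- tresca(field$stress)
  mp <- min_principal(field$stress)
  comp <- .compartment(field$region, lateral_sign * field$centroid[, 1L])
  regions <- c("MFC", "LFC", "MM", "LM", "MTC", "LTC")
  rows <- lapply(regions, function(rg) {
    idx <- which(comp == rg)
    if (!length(idx)) {
      return(data.frame(region = rg, tresca = NA_real_, compressive = NA_real_,
                        sigma3 = NA_real_, el_tresca = NA_integer_,
                        el_compressive = NA_integer_))
    }
    it <- idx[which.max(tr[idx])]
    ic <- idx[which.max(mp$compressive[idx])]
    data.frame(region = rg, tresca = tr[it], compressive = mp$compressive[ic],
               sigma3 = mp$sigma3[ic], el_tresca = it, el_compressive = ic)
  })
  structure(do.call(rbind, rows), class = c("region_peaks", "data.frame"))
}

#' Percent change of a stress value against a reference
#'
#' (value - reference) / reference * 100, rounded to the nearest integer for
#' reporting; use `rounded = FALSE` for full precision.
#'
#' @param value,reference values in consistent units; reference must be
#'   positive.
#' @param rounded round to integer percent (reporting convention).
#' @return percent change.
#' @export
percent_change <- function(value, reference, rounded = TRUE) {
  if (any(reference <= 0)) stop("percent_change: reference must be positive")
  pc <- (value - reference) / reference * 100
  if (rounded) round(pc) else pc
}

#' Build a model-by-region comparison table
#'
#' @param peaks_list named list of `region_peaks` (one per model).
#' @param reference name of the reference model for percent changes (NULL
#'   for none).
#' @param measure "tresca" or "compressive".
#' @return data.frame: rows = models, columns = compartments (+ percent
#'   change columns when a reference is given).
#' @export
comparison_table <- function(peaks_list, reference = NULL,
                             measure = c("tresca", "compressive")) {
  measure <- match.arg(measure)
  regions <- c("MFC", "LFC", "MM", "LM", "MTC", "LTC")
  tab <- do.call(rbind, lapply(names(peaks_list), function(nm) {
    pk <- peaks_list[[nm]]
    vals <- pk[[measure]][match(regions, pk$region)]
    stats::setNames(as.data.frame(as.list(vals)), regions)
  }))
  rownames(tab) <- names(peaks_list)
  if (!is.null(reference)) {
    ref <- tab[reference, ]
    pct <- as.data.frame(lapply(regions, function(rg)
      percent_change(tab[[rg]], ref[[rg]])))
    names(pct) <- paste0("pct_", regions)
    tab <- cbind(tab, pct)
  }
  tab
}

#' Write a stress field to a legacy VTK file
#'
#' Unstructured-grid ASCII VTK with cell arrays `tresca_MPa`,
#' `min_principal_MPa` and `region_id`.
#'
#' @param mesh a `tet_mesh`.
#' @param field a `stress_field` over it.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_vtk_stress <- function(mesh, field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "dlmfem stress field", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", nrow(mesh$nodes))), con)
  utils::write.table(format(mesh$nodes, scientific = TRUE, digits = 8),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  m <- nrow(mesh$tets)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS tresca_MPa float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(tresca(field$stress), digits = 7), con)
  writeLines(c("SCALARS min_principal_MPa float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(min_principal(field$stress)$sigma3, digits = 7), con)
  writeLines(c("SCALARS region_id float 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(field$region))), con)
  invisible(path)
}
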