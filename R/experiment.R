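# Study orchestration: generate the synthetic joint, build the 15-model
# residual family of the discoid lateral meniscus, solve each model under the
# 1150 N stance load, and produce the three result series (equal-ratio,
# equal-volume pairs, fixed-one-part) plus the literature comparison report.

#' Study configuration
#'
#' @param geometry a `knee_config`.
#' @param scheme a `partition_scheme`.
#' @param materials material cards.
#' @param controls solver controls.
#' @param load a `load_case`.
#' @param models character vector of model names to run (default: the full
#'   15-model family).
#' @param smooth_junctions apply [smooth_junction()] to unequal
#'   anterior/posterior models.
#' @param seed integer seed stored in the configuration; the study is fully
#'   deterministic, the seed tags outputs and feeds the geometry config.
#' @return object of class `study_config`.
#' @export
study_config <- function(geometry = knee_config(),
                         scheme = partition_scheme(),
                         materials = default_materials(),
                         controls = solver_controls(),
                         load = load_case(),
                         models = names(enumerate_family()),
                         smooth_junctions = TRUE,
                         seed = 1L) {
  structure(list(geometry = geometry, scheme = scheme, materials = materials,
                 controls = controls, load = load, models = models,
                 smooth_junctions = smooth_junctions, seed = as.integer(seed)),
            class = "study_config")
}

#' Run the resection study
#'
#' Builds the joint once, partitions the discoid lateral meniscus, then for
#' every requested model resects (and smooths) the meniscus, solves the
#' contact problem and extracts per-compartment peak stresses. All models
#' share identical geometry, materials and solver settings except the
#' lateral meniscus solid. Unchanged solids reuse their assembled stiffness.
#'
#' @param config a `study_config`.
#' @param out_dir optional directory: writes the master peak table (CSV), a
#'   study manifest (JSON) and per-model VTK stress fields.
#' @param verbose print per-model progress.
#' @return object of class `study_results`: per-model `region_peaks`,
#'   resection bookkeeping, contact/equilibrium reports, convergence info.
#' @export
run_study <- function(config = study_config(), out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  t_start <- Sys.time()
  geom <- build_knee_geometry(config$geometry)
  lm <- geom$solids$meniscus_lateral
  part <- split_anterior_posterior(partition_rings(lm, config$scheme))
  fam <- enumerate_family()
  unknown <- setdiff(config$models, names(fam))
  if (length(unknown))
    stop("run_study: unknown model name(s): ", paste(unknown, collapse = ", "))
  cache <- new.env(parent = emptyenv())
  peaks <- list(); models <- list(); reports <- list(); failures <- character(0)
  for (nm in config$models) {
    t0 <- Sys.time()
    rm <- resect(part, fam[[nm]])
    if (config$smooth_junctions) rm <- smooth_junction(rm)
    res <- tryCatch({
      model <- build_fe_model(geom, config$materials,
                              lateral_meniscus = rm$solid,
                              controls = config$controls,
                              stiffness_cache = cache)
      st <- solve_static(model, config$load)
      if (!st$converged) stop("model did not converge")
      mesh_all <- merge_meshes(model$meshes)
      fld <- recover_stresses(mesh_all,
                              st$u_full[seq_len(3L * nrow(mesh_all$nodes))],
                              config$materials)
      list(model = model, state = st, field = fld, mesh = mesh_all,
           peaks = region_peaks(fld, config$geometry$lateral_sign),
           report = contact_report(model, st, config$load))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, nm)
      warning("run_study: model ", nm, " failed: ", conditionMessage(res))
      next
    }
    peaks[[nm]] <- res$peaks
    models[[nm]] <- rm
    reports[[nm]] <- res$report
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_vtk_stress(res$mesh, res$field,
                       file.path(out_dir, paste0(nm, "_stress.vtk")))
    }
    if (verbose)
      message(sprintf("  %s: residual %.1f%%, LM peak Tresca %.3f MPa, balance %.2e (%.1fs)",
                      nm, 100 * rm$realized_residual_fraction,
                      res$peaks$tresca[res$peaks$region == "LM"],
                      res$report$balance_error,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out <- structure(list(peaks = peaks, models = models, reports = reports,
                        failures = failures, config = config,
                        partition = part,
                        elapsed = as.numeric(difftime(Sys.time(), t_start,
                                                      units = "secs"))),
                   class = "study_results")
  if (!is.null(out_dir)) {
    utils::write.csv(master_peak_table(out),
                     file.path(out_dir, "peaks.csv"), row.names = FALSE)
    manifest <- list(seed = config$seed, models = config$models,
                     failures = failures,
                     elapsed_seconds = out$elapsed,
                     residual_fractions = vapply(models, function(m)
                       m$realized_residual_fraction, 0))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("study_results: %d models solved (%d failed) in %.1f s\n",
              length(x$peaks), length(x$failures), x$elapsed))
  print(master_peak_table(x), digits = 4)
  invisible(x)
}

#' Master peak table of a study
#' @param results a `study_results`.
#' @return data.frame: one row per model, peak Tresca and compressive stress
#'   per compartment, realized residual fraction.
#' @export
master_peak_table <- function(results) {
  regions <- c("MFC", "LFC", "MM", "LM", "MTC", "LTC")
  rows <- lapply(names(results$peaks), function(nm) {
    pk <- results$peaks[[nm]]
    tr <- stats::setNames(pk$tresca[match(regions, pk$region)],
                          paste0("tresca_", regions))
    cp <- stats::setNames(pk$compressive[match(regions, pk$region)],
                          paste0("compressive_", regions))
    data.frame(model = nm,
               residual_fraction = results$models[[nm]]$realized_residual_fraction,
               as.list(tr), as.list(cp),
               balance_error = results$reports[[nm]]$balance_error)
  })
  do.call(rbind, rows)
}

#' Series 1: equal anterior/posterior residual ratios
#'
#' Peaks and percent change against the intact model over the equal-ratio
#' sequence 100, 85, 70, 55, 40 %.
#'
#' @param results a `study_results` containing the five equal-ratio models.
#' @return list of two data.frames (`tresca`, `compressive`), rows ordered
#'   100 -> 40 %, with percent-change columns against 100a100p.
#' @export
series_equal_ratio <- function(results) {
  members <- c("100a100p", "85a85p", "70a70p", "55a55p", "40a40p")
  missing <- setdiff(members, names(results$peaks))
  if (length(missing))
    stop("series_equal_ratio: missing model(s): ", paste(missing, collapse = ", "))
  pk <- results$peaks[members]
  list(tresca = comparison_table(pk, reference = "100a100p", "tresca"),
       compressive = comparison_table(pk, reference = "100a100p", "compressive"))
}

#' Series 2: equal-volume anterior/posterior pairs (groups A-E)
#'
#' The five pairs with equal total residual volume but mirrored
#' anterior/posterior distribution; reports which member is lower per
#' quantity. Group E is reported without an ordering assertion (the
#' minimum-principal comparison behaves differently from groups A-D in the
#' source observations).
#'
#' @param results a `study_results`.
#' @return named list of groups A-E, each with the pair table and the lower
#'   member per compartment and measure.
#' @export
series_pairs <- function(results) {
  groups <- list(A = c("85a70p", "70a85p"), B = c("85a55p", "55a85p"),
                 C = c("70a55p", "55a70p"), D = c("70a40p", "40a70p"),
                 E = c("55a40p", "40a55p"))
  out <- list()
  for (g in names(groups)) {
    mem <- groups[[g]]
    missing <- setdiff(mem, names(results$peaks))
    if (length(missing))
      stop("series_pairs: missing model(s): ", paste(missing, collapse = ", "))
    pk <- results$peaks[mem]
    tab_t <- comparison_table(pk, NULL, "tresca")
    tab_c <- comparison_table(pk, NULL, "compressive")
    lower <- function(tab) {
      vapply(names(tab), function(rg)
        rownames(tab)[which.min(tab[[rg]])], "")
    }
    out[[g]] <- list(members = mem, tresca = tab_t, compressive = tab_c,
                     lower_tresca = lower(tab_t),
                     lower_compressive = lower(tab_c),
                     assert_ordering = g != "E")
  }
  out
}

#' Series 3: one part fixed, the other sequentially reduced
#'
#' Four groups with fixed anterior fraction (85/70/55/40 %) and decreasing
#' posterior fraction, and the transposed four groups with fixed posterior.
#'
#' @param results a `study_results`.
#' @return list with `fixed_anterior` and `fixed_posterior`, each a named
#'   list of comparison tables.
#' @export
series_fixed_one <- function(results) {
  fixed_ant <- list(
    `85` = c("85a85p", "85a70p", "85a55p"),
    `70` = c("70a85p", "70a70p", "70a55p", "70a40p"),
    `55` = c("55a85p", "55a70p", "55a55p", "55a40p"),
    `40` = c("40a70p", "40a55p", "40a40p"))
  fixed_post <- list(
    `85` = c("85a85p", "70a85p", "55a85p"),
    `70` = c("85a70p", "70a70p", "55a70p", "40a70p"),
    `55` = c("85a55p", "70a55p", "55a55p", "40a55p"),
    `40` = c("70a40p", "55a40p", "40a40p"))
  build <- function(gl) {
    lapply(gl, function(mem) {
      missing <- setdiff(mem, names(results$peaks))
      if (length(missing))
        stop("series_fixed_one: missing model(s): ",
             paste(missing, collapse = ", "))
      pk <- results$peaks[mem]
      list(members = mem,
           tresca = comparison_table(pk, NULL, "tresca"),
           compressive = comparison_table(pk, NULL, "compressive"))
    })
  }
  list(fixed_anterior = build(fixed_ant), fixed_posterior = build(fixed_post))
}

#' Literature comparison constants
#'
#' Whole-joint peak stresses (MPa) reported by three knee finite-element
#' studies: peak shear (SS) and compressive (CS) stress on femoral cartilage
#' (FC), menisci (M) and tibial cartilage (TC).
#'
#' @return data.frame of the three literature rows.
#' @export
literature_validation_table <- function() {
  data.frame(
    study = c("reference_model", "zhi_xu", "zhang_k"),
    SSFC = c(1.42, 1.72, 2.00),
    SSM = c(7.61, 11.45, 6.72),
    SSTC = c(2.85, 3.56, 2.40),
    CSFC = c(3.11, 6.51, 4.25),
    CSM = c(5.90, 6.61, 9.15),
    CSTC = c(3.36, 8.45, 6.81))
}

#' Compare the intact model against literature peak-stress spans
#'
#' Tabulates the intact (100a100p) whole-tissue peaks against the three
#' literature rows and flags quantities outside the plausibility band
#' [0.5 x min, 2 x max]; the flags are report-only, never a failure. Peaks
#' are reported in both scopes where the sources are ambiguous: the
#' whole-meniscus peak (MM and LM together) is the tabulated SSM/CSM.
#'
#' @param results a `study_results` containing 100a100p.
#' @return data.frame: quantity, model value, literature span, flag.
#' @export
validate_against_literature <- function(results) {
  if (!"100a100p" %in% names(results$peaks))
    stop("validate_against_literature: study lacks the intact model")
  pk <- results$peaks[["100a100p"]]
  val <- function(regs, col) max(pk[[col]][pk$region %in% regs], na.rm = TRUE)
  model_vals <- c(
    SSFC = val(c("MFC", "LFC"), "tresca"),
    SSM = val(c("MM", "LM"), "tresca"),
    SSTC = val(c("MTC", "LTC"), "tresca"),
    CSFC = val(c("MFC", "LFC"), "compressive"),
    CSM = val(c("MM", "LM"), "compressive"),
    CSTC = val(c("MTC", "LTC"), "compressive"))
  lit <- literature_validation_table()
  rows <- lapply(names(model_vals), function(qn) {
    span <- range(lit[[qn]])
    band <- c(0.5 * span[1L], 2 * span[2L])
    data.frame(quantity = qn, model = model_vals[[qn]],
               lit_min = span[1L], lit_max = span[2L],
               band_low = band[1L], band_high = band[2L],
               within_band = model_vals[[qn]] >= band[1L] &
                             model_vals[[qn]] <= band[2L])
  })
  do.call(rbind, rows)
}
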