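#' Write study results with a checksummed manifest
#'
#' Emits the per-patient results CSV, the four group tables
#' (`table_morphology.csv` ... `table_wss.csv`), a failures CSV when any
#' patient failed, a JSON summary, and `manifest.json` listing every file
#' with its MD5 checksum plus the solver settings and master seed. Two runs
#' with identical inputs produce identical checksums.
#'
#' @param result A `study_result` from [run_study()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest (list), invisibly.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_domain(paste0("cannot create ", out_dir))
  files <- character()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(as.data.frame(df), p, row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
  }
  pat <- result$patients
  drop <- vapply(pat, is.list, logical(1))
  w(pat[, !drop, drop = FALSE], "patients.csv")
  if (!is.null(result$tables))
    for (nm in names(result$tables))
      w(result$tables[[nm]], paste0("table_", nm, ".csv"))
  if (nrow(result$failures)) w(result$failures, "failures.csv")
  sm <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(n_patients = nrow(result$patients),
         n_failed = nrow(result$failures),
         alpha = result$alpha, mesh_size = result$mesh_size,
         solver = unclass(result$solver_config)),
    sm, auto_unbox = TRUE, digits = NA)
  files <- c(files, sm)
  manifest <- list(
    files = lapply(files, function(p)
      list(name = basename(p), md5 = unname(tools::md5sum(p)))),
    seed = result$seed,
    solver = unclass(result$solver_config),
    package_version = as.character(utils::packageVersion("hemoflow")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Export a solution snapshot as legacy ASCII VTK
#'
#' Writes the cell-centered speed, shear rate, viscosity and pressure of
#' one stored snapshot as a STRUCTURED_POINTS legacy VTK file for
#' inspection in ParaView. Solid cells carry zeros.
#'
#' @param solution A `flow_solution`.
#' @param path Output `.vtk` path.
#' @param time_index Snapshot index (default peak systole).
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(solution, path,
                               time_index = solution$peak_systole_index) {
  dom <- solution$domain
  d <- solution_fields(solution, time_index)
  full <- function(v) {
    m <- matrix(0, dom$nx, dom$ny)
    m[dom$fluid] <- v
    m
  }
  lines <- c("# vtk DataFile Version 3.0",
             sprintf("hemoflow snapshot t=%.6g s", solution$times[time_index]),
             "ASCII", "DATASET STRUCTURED_POINTS",
             sprintf("DIMENSIONS %d %d 1", dom$nx, dom$ny),
             sprintf("ORIGIN %.9g %.9g 0", dom$xc[1], dom$yc[1]),
             sprintf("SPACING %.9g %.9g 1", dom$h, dom$h),
             sprintf("POINT_DATA %d", dom$nx * dom$ny))
  add_scalar <- function(name, m) {
    c(sprintf("SCALARS %s float 1", name), "LOOKUP_TABLE default",
      sprintf("%.6g", as.vector(m)))
  }
  lines <- c(lines,
             add_scalar("speed", full(d$speed)),
             add_scalar("shear_rate", full(d$shear_rate)),
             add_scalar("viscosity", full(d$viscosity)),
             add_scalar("pressure", full(d$pressure)))
  writeLines(lines, path)
  invisible(path)
}
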