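# Plain-text exports: sweep tables and probe series as CSV, fields as
# legacy ASCII VTK point clouds (facet centres / cell centres), run
# configuration as JSON.

#' Write / read a sweep result table
#'
#' The CSV mirrors the redistribution result table (family, epsilon, DRA
#' direction, areas in mm^2, normalized low-WSS area); the protocol
#' attributes travel in a commented header line.
#'
#' @param sweep an `avf_sweep`.
#' @param path file path.
#' @return the path (writer) or the `avf_sweep` (reader).
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "avf_sweep"))
  pr <- attr(sweep, "protocol")
  hdr <- sprintf("# avfwss sweep: mode=%s instant=%s mesh=%s n=%d h=%.6g",
                 pr$mode, pr$instant, pr$mesh_level, pr$n_elements, pr$h)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(sweep), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  if (!file.exists(path)) stop("sweep file not found: ", path)
  out <- read.csv(path, comment.char = "#")
  class(out) <- c("avf_sweep", "data.frame")
  attr(out, "protocol") <- list(mode = "unknown", instant = "unknown",
                                mesh_level = "unknown",
                                n_elements = NA, h = NA)
  out
}

#' Export a WSS field as a legacy ASCII VTK point cloud
#'
#' One point per wall facet (facet centre) with the WSS vector and
#' magnitude, loadable in ParaView.
#'
#' @param field an `avf_wss` field.
#' @param path output `.vtk` file.
#' @return the path, invisibly.
#' @export
write_wss_vtk <- function(field, path) {
  stopifnot(inherits(field, "avf_wss"))
  n <- nrow(field)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "avfwss wall shear stress", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  write(t(cbind(field$cx, field$cy, field$cz)), con, ncolumns = 3)
  writeLines(c(sprintf("VERTICES %d %d", n, 2 * n)), con)
  write(t(cbind(1L, seq_len(n) - 1L)), con, ncolumns = 2)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS wss_magnitude float 1",
               "LOOKUP_TABLE default"), con)
  write(field$mag, con, ncolumns = 6)
  writeLines("VECTORS wss float", con)
  write(t(cbind(field$tau_x, field$tau_y, field$tau_z)), con, ncolumns = 3)
  invisible(path)
}

#' Export a velocity/pressure snapshot as a legacy ASCII VTK point cloud
#'
#' @param mesh the `avf_mesh`.
#' @param solution an `avf_flow`.
#' @param path output `.vtk` file.
#' @param instant stored instant index (default 1).
#' @return the path, invisibly.
#' @export
write_velocity_vtk <- function(mesh, solution, path, instant = 1L) {
  U <- solution$fields[[instant]]$U
  p <- solution$fields[[instant]]$p
  idx <- arrayInd(which(mesh$cellcode == 0L), mesh$dims)
  xyz <- sweep((idx - 0.5) * mesh$h, 2, mesh$x0, "+")
  n <- nrow(xyz)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "avfwss velocity field",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  write(t(xyz), con, ncolumns = 3)
  writeLines(sprintf("VERTICES %d %d", n, 2 * n), con)
  write(t(cbind(1L, seq_len(n) - 1L)), con, ncolumns = 2)
  writeLines(c(sprintf("POINT_DATA %d", n), "SCALARS pressure float 1",
               "LOOKUP_TABLE default"), con)
  write(p, con, ncolumns = 6)
  writeLines("VECTORS velocity float", con)
  write(t(U), con, ncolumns = 3)
  invisible(path)
}

#' Write probe time series to CSV
#'
#' @param series an `avf_probe_series`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_probe_csv <- function(series, path) {
  stopifnot(inherits(series, "avf_probe_series"))
  nv <- ncol(series$vel_axial)
  nw <- ncol(series$wss_mag)
  df <- data.frame(t = series$t)
  for (i in seq_len(nv)) df[[paste0("v_axial_", i)]] <- series$vel_axial[, i]
  for (i in seq_len(nw)) df[[paste0("wss_mag_", i)]] <- series$wss_mag[, i]
  for (i in seq_len(nw)) df[[paste0("wss_axial_", i)]] <- series$wss_axial[, i]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a JSON run configuration
#'
#' Recognized keys: `diameters_mm` (length 3: PRA, DRA, CV), `angle_deg`,
#' `extensions_D` (length 3), `spline_smoothness`, `mesh_level`,
#' `cv_pressure_mmhg`, `density`, `viscosity`.
#'
#' @param path JSON file.
#' @return list with `params` ([avf_params()]), `mesh_level`, `fluid` and
#'   `cv_pressure` (Pa).
#' @export
read_config_json <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  dm <- if (!is.null(cfg$diameters_mm)) mm_to_m(cfg$diameters_mm)
        else c(3.0e-3, 1.2e-3, 5.0e-3)
  ext <- if (!is.null(cfg$extensions_D)) cfg$extensions_D else c(10, 10, 10)
  params <- avf_params(
    d_pra = dm[1], d_dra = dm[2], d_cv = dm[3],
    angle_deg = if (!is.null(cfg$angle_deg)) cfg$angle_deg else 45,
    ext_pra = ext[1], ext_dra = ext[2], ext_cv = ext[3],
    spline_smoothness = if (!is.null(cfg$spline_smoothness))
      cfg$spline_smoothness else 0.25)
  fluid <- fluid_properties(
    density = if (!is.null(cfg$density)) cfg$density else 1050,
    viscosity = if (!is.null(cfg$viscosity)) cfg$viscosity else 4.0e-3)
  list(params = params,
       mesh_level = if (!is.null(cfg$mesh_level)) cfg$mesh_level
                    else "coarse",
       fluid = fluid,
       cv_pressure = if (!is.null(cfg$cv_pressure_mmhg))
         mmhg_to_pa(cfg$cv_pressure_mmhg) else 1064)
}
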