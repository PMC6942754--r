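# Run artefacts: mesh/field export in legacy VTK ASCII (readable by ParaView
# and meshio), membrane time-series CSVs, and the JSON run manifest.

#' Export the mesh (and optional cell fields) as legacy ASCII VTK
#'
#' @param mesh an `ep_mesh`.
#' @param path output `.vtk` file.
#' @param cell_data named list of per-triangle numeric vectors (e.g. field
#'   magnitude snapshots).
#' @param point_data named list of per-node numeric vectors (length
#'   `n_nodes`; duplicated interface DOFs are averaged onto their node).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  n <- mesh$n_nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "porefield mesh export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(cbind(mesh$nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  m <- nrow(mesh$tri)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  utils::write.table(cbind(3L, mesh$tri - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(5L, m)), con)       # VTK_TRIANGLE
  cell_data <- c(list(region = as.integer(factor(mesh$region))), cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(cell_data[[nm]], digits = 10), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]][seq_len(n)]
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(v, digits = 10), con)
    }
  }
  invisible(path)
}

#' Write per-membrane time series to CSV
#'
#' Long format: one row per (time, contour node) with the transmembrane
#' voltage, pore density, representative pore radius and electroporation
#' conductance.
#'
#' @param sim an `ep_sim`.
#' @param which membrane name.
#' @param path output CSV.
#' @param every write every k-th time step (the full series is large).
#' @return `path`, invisibly.
#' @export
write_membrane_csv <- function(sim, which, path, every = 5L) {
  m <- sim$mem[[which]]
  f <- sim$ctx$ifaces[[which]]
  rows <- seq(1, length(sim$t), by = every)
  df <- do.call(rbind, lapply(rows, function(k) data.frame(
    t = sim$t[k], theta = f$theta, V_m = m$u[k, ],
    N = m$N[k, ], r_pore = m$r[k, ], g_ep = m$g_ep[k, ])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the poration summary CSV
#'
#' Columns `t, S_outer, S_inner, flux_outer, flux_inner`.
#'
#' @param sim an `ep_sim`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_poration_csv <- function(sim, path) {
  So <- electroporated_area(sim, "outer")
  Si <- electroporated_area(sim, "inner")
  df <- data.frame(t = So$t, S_outer = So$S, S_inner = Si$S,
                   flux_outer = permeabilized_flux(So)$flux,
                   flux_inner = permeabilized_flux(Si)$flux)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of the run: config snapshot (flat SI keys), seed, package
#' version, mesh statistics, wall time, and an inventory of output files
#' with their md5 checksums.  Re-running with the same config and seed
#' reproduces every checksum.
#'
#' @param params the `ep_params` used.
#' @param seed the run seed.
#' @param mesh the `ep_mesh` used.
#' @param out_dir directory containing the outputs to inventory.
#' @param files character vector of file names (relative to `out_dir`).
#' @param wall_time elapsed seconds.
#' @param path manifest path; default `manifest.json` inside `out_dir`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, seed, mesh, out_dir, files,
                           wall_time = NA_real_,
                           path = file.path(out_dir, "manifest.json")) {
  km <- .pf_key_map()
  cfg <- lapply(km, function(pp) .pf_get_path(params, pp))
  cfg <- cfg[!vapply(cfg, function(v) is.null(v) || (is.numeric(v) && is.na(v)), logical(1))]
  inv <- lapply(files, function(f) {
    fp <- file.path(out_dir, f)
    list(file = f, md5 = unname(tools::md5sum(fp)), bytes = file.size(fp))
  })
  obj <- list(
    package = "porefield",
    version = as.character(utils::packageVersion("porefield")),
    seed = seed,
    config = cfg,
    mesh = list(n_nodes = mesh$n_nodes, n_tri = nrow(mesh$tri),
                n_dof = mesh$n_dof, min_angle_deg = mesh$min_angle),
    wall_time_s = wall_time,
    outputs = inv
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
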