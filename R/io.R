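#' Output writers
#'
#' Field snapshots can be written as VTK legacy structured-points files
#' (ASCII, loadable in standard viewers) for visualisation, as an exact
#' binary archive for lossless round-trips, and as CSV for the scalar
#' diagnostic time series.  Every output directory also receives the exact
#' parameter set used, for provenance.
#'
#' @name output_io
NULL

#' Write one snapshot as a VTK legacy structured-points file
#'
#' Cell data: thetaB, thetaT, pressure, ADP, all chemical fields, and the
#' cell-centred velocity vector.
#'
#' @param snapshot one element of a bundle's `snapshots`
#' @param mesh a `clot_mesh`
#' @param path output file path (`.vtk`)
#' @return the path, invisibly
#' @export
write_vtk_snapshot <- function(snapshot, mesh, path) {
  nx <- mesh$nx; ny <- mesh$ny
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl(sprintf("clotsim fields t=%.6f s (units: um, s, nM, platelets/um^3)",
             snapshot$t))
  wl("ASCII")
  wl("DATASET STRUCTURED_POINTS")
  wl(sprintf("DIMENSIONS %d %d 1", nx + 1, ny + 1))
  wl(sprintf("ORIGIN %g %g 0", min(mesh$x_faces), min(mesh$y_faces)))
  wl(sprintf("SPACING %g %g 1", mesh$dx, mesh$dy))
  wl(sprintf("CELL_DATA %d", nx * ny))
  scalar <- function(name, m) {
    wl(sprintf("SCALARS %s double 1", name))
    wl("LOOKUP_TABLE default")
    writeLines(format(as.numeric(m), digits = 9), con)
  }
  scalar("thetaB", snapshot$theta_B)
  scalar("thetaT", snapshot$theta_T)
  scalar("p", snapshot$p)
  scalar("ADP", snapshot$adp)
  for (nm in names(snapshot$chem)) scalar(nm, snapshot$chem[[nm]])
  uc <- (snapshot$u[seq_len(nx), , drop = FALSE] +
         snapshot$u[2:(nx + 1), , drop = FALSE]) / 2
  vc <- (snapshot$v[, seq_len(ny), drop = FALSE] +
         snapshot$v[, 2:(ny + 1), drop = FALSE]) / 2
  wl("VECTORS U double")
  writeLines(paste(format(as.numeric(uc), digits = 9),
                   format(as.numeric(vc), digits = 9), "0"), con)
  invisible(path)
}

#' Write a full output bundle to a directory
#'
#' Writes the exact configuration (`inputParameters`), the scalar time
#' series (`series.csv`), an exact archive of the bundle (`bundle.rds`) and
#' one VTK file per snapshot.
#'
#' @param bundle a `clot_output_bundle`
#' @param dir output directory (created if needed)
#' @param vtk write per-snapshot VTK files
#' @return `dir`, invisibly
#' @export
write_output_bundle <- function(bundle, dir, vtk = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_input_parameters(bundle$config$params,
                         file.path(dir, "inputParameters"))
  utils::write.csv(bundle$series, file.path(dir, "series.csv"),
                   row.names = FALSE)
  saveRDS(bundle, file.path(dir, "bundle.rds"))
  if (vtk)
    for (k in seq_along(bundle$snapshots))
      write_vtk_snapshot(bundle$snapshots[[k]], bundle$mesh,
                         file.path(dir, sprintf("fields_%06.2fs.vtk",
                                                bundle$times[k])))
  invisible(dir)
}

#' Read back an output bundle archive
#'
#' @param dir directory written by [write_output_bundle()]
#' @return the `clot_output_bundle` (lossless round-trip)
#' @export
read_output_bundle <- function(dir) readRDS(file.path(dir, "bundle.rds"))

#' Parse a VTK legacy structured-points file written by this package
#'
#' Minimal reader used for round-trip checking: returns the grid dimensions
#' and the named cell-data scalars.
#'
#' @param path `.vtk` file
#' @return list with `dims` and named list `scalars` of `nx x ny` matrices
#' @export
read_vtk_snapshot <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(grep("^DIMENSIONS", lines, value = TRUE),
                              " ")[[1]][2:3])
  nx <- dims[1] - 1L; ny <- dims[2] - 1L
  n <- nx * ny
  scalars <- list()
  k <- grep("^SCALARS", lines)
  for (i in k) {
    nm <- strsplit(lines[i], " ")[[1]][2]
    vals <- as.numeric(lines[(i + 2):(i + 1 + n)])
    scalars[[nm]] <- matrix(vals, nx, ny)
  }
  list(dims = dims, scalars = scalars)
}
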