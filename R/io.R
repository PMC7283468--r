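#' Write a cell mesh as legacy ASCII VTK polydata
#'
#' Includes optional per-triangle cell data (e.g. actin concentration,
#' region labels) and per-node point data, for inspection in standard
#' scientific visualization tools.
#'
#' @param mesh a `cell_mesh`.
#' @param file output path.
#' @param cell_data named list of per-triangle numeric vectors.
#' @param point_data named list of per-node numeric vectors.
#' @return `file`, invisibly.
#' @export
write_vtk_polydata <- function(mesh, file, cell_data = list(),
                               point_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$pos); nt <- nrow(mesh$tris)
  writeLines(c("# vtk DataFile Version 3.0", "cell cortex", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$pos, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nt, 4L * nt), con)
  utils::write.table(cbind(3L, mesh$tris - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", nt), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(cell_data[[nm]]), digits = 10), con)
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(point_data[[nm]]), digits = 10), con)
    }
  }
  invisible(file)
}

#' Write a cell mesh in OFF format
#' @param mesh a `cell_mesh`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_off <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d %d", nrow(mesh$pos), nrow(mesh$tris), 0)),
             con)
  utils::write.table(format(mesh$pos, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$tris - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a mesh from OFF format
#' @param file path to an OFF file.
#' @return a `cell_mesh`.
#' @export
read_off <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file", call. = FALSE)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  pos <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                     quiet = TRUE), nv, 3, byrow = TRUE)
  fl <- matrix(scan(text = paste(lines[(3 + nv):(2 + nv + nf)], collapse = "\n"),
                    quiet = TRUE), nf, 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("only triangle faces supported", call. = FALSE)
  mesh_from_triangulation(pos, fl[, 2:4] + 1L)
}

#' Write a run metrics log to CSV
#' @param sim a `cell_sim` (or a metrics data.frame).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_metrics_csv <- function(sim, file) {
  m <- if (inherits(sim, "cell_sim")) sim$metrics else sim
  utils::write.csv(m, file, row.names = FALSE)
  invisible(file)
}

#' Write a run manifest to CSV
#' @param manifest data.frame from [enumerate_conditions()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_manifest_csv <- function(manifest, file) {
  utils::write.csv(manifest, file, row.names = FALSE)
  invisible(file)
}

#' Checkpoint / restore a simulation state
#'
#' Serializes the full `sim_state` (mesh, populations, clock, RNG-free
#' state) so long runs can be resumed.
#'
#' @param state a `sim_state`.
#' @param file path.
#' @return `file` (save) or the restored `sim_state` (load).
#' @export
save_state <- function(state, file) {
  stopifnot(inherits(state, "sim_state"))
  saveRDS(state, file)
  invisible(file)
}

#' @rdname save_state
#' @export
load_state <- function(file) {
  st <- readRDS(file)
  if (!inherits(st, "sim_state")) stop("not a saved sim_state", call. = FALSE)
  st
}
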