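#' Write a volume mesh (with optional fields) as a legacy VTK file
#'
#' ASCII legacy VTK unstructured grid; tet4 cells are written as VTK type 10
#' and tet10 as type 24.  Point data and cell data may be scalars (numeric
#' vectors) or vectors (3-column matrices).
#'
#' @param mesh a `volume_mesh`.
#' @param path output `.vtk` path.
#' @param point_data named list of per-node data.
#' @param cell_data named list of per-element data.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  npe <- ncol(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "orthofem unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, m * (npe + 1L)), con)
  utils::write.table(cbind(npe, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(if (npe == 4L) 10L else 24L, m)), con)

  write_fields <- function(fields, count, kind) {
    if (!length(fields)) return(invisible())
    writeLines(sprintf("%s %d", kind, count), con)
    for (nm in names(fields)) {
      val <- fields[[nm]]
      if (is.matrix(val) && ncol(val) == 3) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(format(val, digits = 17, trim = TRUE), con,
                           row.names = FALSE, col.names = FALSE,
                           quote = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(as.numeric(val), digits = 17, trim = TRUE), con)
      }
    }
  }
  write_fields(point_data, n, "POINT_DATA")
  write_fields(cell_data, m, "CELL_DATA")
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid of tetrahedra
#'
#' Supports the subset written by [write_vtk()] (tet4/tet10 cells; field
#' data are ignored).
#'
#' @param path `.vtk` file path.
#' @return a `volume_mesh` (without region tags or node sets).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("not a legacy VTK unstructured grid: POINTS missing")
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):length(lines)], n = 3 * n,
              quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  hdr <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2:3])
  vals <- scan(text = lines[(ic + 1):length(lines)], n = hdr[2],
               quiet = TRUE)
  npe <- vals[1]
  cm <- matrix(as.integer(vals), ncol = npe + 1L, byrow = TRUE)
  if (!all(cm[, 1] == npe)) stop("mixed cell sizes are not supported")
  elems <- cm[, -1L, drop = FALSE] + 1L
  new_volume_mesh(nodes, elems, rep("unknown", nrow(elems)),
                  order = if (npe == 4L) 1L else 2L)
}

#' Export a volume mesh in Abaqus-style .inp format
#'
#' Writes `*NODE`, `*ELEMENT` (C3D4 or C3D10) with one `*ELSET` per region
#' and one `*NSET` per node set, for cross-checking in third-party FE tools.
#'
#' @param mesh a `volume_mesh`.
#' @param path output `.inp` path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.10g, %.10g, %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  type <- if (mesh$order == 1L) "C3D4" else "C3D10"
  for (reg in unique(mesh$region)) {
    idx <- which(mesh$region == reg)
    writeLines(sprintf("*ELEMENT, TYPE=%s, ELSET=%s", type, toupper(reg)),
               con)
    writeLines(apply(cbind(idx, mesh$elems[idx, , drop = FALSE]), 1,
                     paste, collapse = ", "), con)
  }
  for (nm in names(mesh$node_sets)) {
    writeLines(sprintf("*NSET, NSET=%s", toupper(nm)), con)
    ids <- mesh$node_sets[[nm]]
    chunks <- split(ids, ceiling(seq_along(ids) / 12))
    writeLines(vapply(chunks, paste, character(1), collapse = ", "), con)
  }
  invisible(path)
}
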