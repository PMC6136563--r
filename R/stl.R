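#' Write a triangulated surface to STL
#'
#' Binary (default) or ASCII STL.  Binary STL stores float32 coordinates,
#' so round-trip fidelity is ~1e-6 mm for coordinates below 16 mm in
#' magnitude; ASCII output uses 9 significant digits.
#'
#' @param surf a `tri_surface`.
#' @param path output file path.
#' @param binary write binary STL (TRUE) or ASCII (FALSE).
#' @param name solid name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surf, path, binary = TRUE, name = "surface") {
  v <- surf$vertices; f <- surf$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n <- n / ifelse(len > 0, len, 1)
  nf <- nrow(f)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC(name, width = -80))
    writeBin(header[seq_len(80)], con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # interleave: normal, v1, v2, v3 per facet as float32, then uint16 attr
    dat <- t(cbind(n, a, b, c_))          # 12 x nf, column-major per facet
    fl <- writeBin(as.numeric(dat), raw(), size = 4, endian = "little")
    m <- rbind(matrix(fl, nrow = 48L),
               matrix(as.raw(0), nrow = 2L, ncol = nf))
    writeBin(as.vector(m), con)
  } else {
    fmt <- function(m) apply(m, 1, function(r)
      paste(formatC(r, format = "g", digits = 9), collapse = " "))
    lines <- c(paste("solid", name),
               paste0("  facet normal ", fmt(n), "\n",
                      "    outer loop\n",
                      "      vertex ", fmt(a), "\n",
                      "      vertex ", fmt(b), "\n",
                      "      vertex ", fmt(c_), "\n",
                      "    endloop\n",
                      "  endfacet"),
               paste("endsolid", name))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' Vertices that coincide exactly are merged so that closed solids read back
#' as connected surfaces.  Malformed binary files raise an error reporting
#' the byte offset at which the file was truncated.
#'
#' @param path STL file path.
#' @return a `tri_surface`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = min(sz, 512))
  is_ascii <- identical(rawToChar(raw[1:5]), "solid") &&
    grepl("facet", rawToChar(raw), fixed = TRUE, useBytes = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  new_tri_surface(unname(verts), faces)
}

read_stl_binary <- function(path, sz) {
  if (sz < 84)
    stop("malformed binary STL: file truncated at byte ", sz,
         " (header incomplete)")
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", size = 4, endian = "little")
  expected <- 84 + 50 * nf
  if (sz < expected)
    stop("malformed binary STL: expected ", expected, " bytes for ", nf,
         " facets, file truncated at byte ", sz)
  body <- readBin(con, "raw", n = 50L * nf)
  if (length(body) < 50L * nf)
    stop("malformed binary STL: truncated facet data at byte ",
         84 + length(body))
  m <- matrix(body, nrow = 50L)
  vals <- readBin(as.vector(m[1:48, , drop = FALSE]), "numeric",
                  n = 12L * nf, size = 4, endian = "little")
  per <- matrix(vals, nrow = 12L)        # normal + 3 vertices per facet
  tri <- matrix(0, nf * 3L, 3L)
  tri[seq(1, 3 * nf, by = 3), ] <- t(per[4:6, , drop = FALSE])
  tri[seq(2, 3 * nf, by = 3), ] <- t(per[7:9, , drop = FALSE])
  tri[seq(3, 3 * nf, by = 3), ] <- t(per[10:12, , drop = FALSE])
  tri
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL: vertex count ", length(vl),
         " is not a multiple of 3")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4]))
  do.call(rbind, nums)
}

#' Export an anatomy model as STL files plus a JSON sidecar
#'
#' Writes one STL per tissue region and a `landmarks.json` sidecar holding
#' landmark, bracket and TAD coordinates.
#'
#' @param model an `anatomy_model`.
#' @param dir output directory (created if needed).
#' @param binary write binary STL.
#' @return named character vector of the files written, invisibly.
#' @export
export_stl <- function(model, dir, binary = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(names(model$surfaces), function(nm) {
    p <- file.path(dir, paste0(nm, ".stl"))
    write_stl(model$surfaces[[nm]], p, binary = binary, name = nm)
    p
  }, character(1))
  side <- list(landmarks = apply(model$landmarks, 1, as.numeric,
                                 simplify = FALSE),
               bracket_point = as.numeric(model$bracket_point),
               tad_point = as.numeric(model$tad_point))
  sp <- file.path(dir, "landmarks.json")
  jsonlite::write_json(side, sp, auto_unbox = FALSE, digits = NA)
  invisible(c(files, landmarks = sp))
}

#' Import a single STL surface
#'
#' @param path STL file path.
#' @return a `tri_surface`.
#' @export
import_stl <- function(path) read_stl(path)
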