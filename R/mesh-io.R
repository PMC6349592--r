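# Surface and volume mesh I/O. Supported surface formats: STL (ASCII and
# binary), PLY (ASCII, with optional per-face integer labels), OFF, and
# legacy-ASCII VTK POLYDATA. Tet meshes and nodal fields are written as
# legacy-ASCII VTK UNSTRUCTURED_GRID. Vertices and faces round-trip within
# float precision; port tags are not serialized.

meshFormatFromPath <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("stl", "ply", "off", "vtk"))
    stop("unsupported mesh format '", ext,
         "': supported formats are STL, PLY, OFF, VTK (legacy ASCII)")
  ext
}

#' Read a surface mesh
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format one of \code{"stl"}, \code{"ply"}, \code{"off"},
#'   \code{"vtk"}.
#' @return a \linkS4class{TriSurfaceMesh}. STL files have duplicated corner
#'   vertices merged exactly; PLY and VTK per-face integer labels are
#'   restored when present.
#' @export
readMesh <- function(path, format = meshFormatFromPath(path)) {
  force(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         stl = readSTL(path),
         ply = readPLY(path),
         off = readOFF(path),
         vtk = readVTKSurface(path))
}

#' Write a surface or tetrahedral mesh
#'
#' @param mesh a \linkS4class{TriSurfaceMesh} or \linkS4class{TetMesh}
#'   (the latter is always written as legacy VTK).
#' @param path output file path.
#' @param format surface format; inferred from the extension by default.
#' @param binary write binary STL instead of ASCII.
#' @return \code{path}, invisibly.
#' @export
writeMesh <- function(mesh, path, format = meshFormatFromPath(path),
                      binary = FALSE) {
  if (is(mesh, "TetMesh")) {
    writeVTKTetMesh(mesh, path)
    return(invisible(path))
  }
  switch(format,
         stl = writeSTL(mesh, path, binary = binary),
         ply = writePLY(mesh, path),
         off = writeOFF(mesh, path),
         vtk = writeVTKSurface(mesh, path))
  invisible(path)
}

mergeDuplicateVertices <- function(v, f) {
  key <- paste(v[, 1], v[, 2], v[, 3])
  first <- !duplicated(key)
  remap <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  f2 <- matrix(remap[f], ncol = 3)
  list(v = v2, f = f2)
}

readSTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  sz <- file.info(path)$size
  isBinary <- length(ntri) == 1 && !is.na(ntri) && sz == 84 + 50 * ntri
  if (isBinary) {
    tri <- matrix(0, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("malformed ASCII STL: vertex count not a multiple of 3 (",
           length(vl), " vertex lines)")
    tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
  }
  f <- matrix(seq_len(nrow(tri)), ncol = 3, byrow = TRUE)
  m <- mergeDuplicateVertices(tri, f)
  triSurfaceMesh(m$v, m$f)
}

writeSTL <- function(mesh, path, binary = FALSE) {
  v <- mesh@vertices; f <- mesh@faces
  n <- faceNormals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[i, ], t(v[f[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    out <- c("solid atriflow",
             unlist(lapply(seq_len(nrow(f)), function(i) c(
               sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
               "  outer loop",
               sprintf("    vertex %.9g %.9g %.9g",
                       v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
               "  endloop", "endfacet"))),
             "endsolid atriflow")
    writeLines(out, path)
  }
}

readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("malformed PLY: missing 'ply' magic at line 1")
  hEnd <- which(lines == "end_header")[1]
  if (is.na(hEnd)) stop("malformed PLY: no end_header")
  header <- lines[seq_len(hEnd)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  hasLabel <- any(grepl("^property (int|uchar|uint) label", header))
  vlines <- lines[(hEnd + 1):(hEnd + nv)]
  v <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(p)
    as.numeric(p[1:3])))
  flines <- lines[(hEnd + nv + 1):(hEnd + nv + nf)]
  fparsed <- lapply(strsplit(trimws(flines), "\\s+"), as.numeric)
  if (any(vapply(fparsed, function(p) p[1] != 3, logical(1))))
    stop("malformed PLY: only triangular faces are supported")
  f <- do.call(rbind, lapply(fparsed, function(p) p[2:4] + 1))
  lab <- if (hasLabel) as.integer(vapply(fparsed, function(p) p[5], numeric(1)))
         else integer(0)
  triSurfaceMesh(v, f, faceLabels = lab)
}

writePLY <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  hasLabel <- length(mesh@faceLabels) == nrow(f) && nrow(f) > 0
  header <- c("ply", "format ascii 1.0",
              paste("element vertex", nrow(v)),
              "property float x", "property float y", "property float z",
              paste("element face", nrow(f)),
              "property list uchar int vertex_indices",
              if (hasLabel) "property int label",
              "end_header")
  vl <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  fl <- if (hasLabel)
    sprintf("3 %d %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L, mesh@faceLabels)
  else sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(header, vl, fl), path)
}

readOFF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (toupper(trimws(lines[1])) != "OFF")
    stop("malformed OFF: missing OFF magic at line 1")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  v <- do.call(rbind, lapply(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  fp <- lapply(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+"), as.numeric)
  if (any(vapply(fp, function(p) p[1] != 3, logical(1))))
    stop("malformed OFF: only triangular faces are supported")
  f <- do.call(rbind, lapply(fp, function(p) p[2:4] + 1))
  triSurfaceMesh(v, f)
}

writeOFF <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  writeLines(c("OFF", paste(nrow(v), nrow(f), 0),
               sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             path)
}

readVTKSurface <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("malformed VTK: no POINTS section")
  nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  vals <- scan(text = paste(lines[(ip + 1):length(lines)], collapse = "\n"),
               n = 3 * nv, quiet = TRUE)
  v <- matrix(vals, ncol = 3, byrow = TRUE)
  ipoly <- grep("^POLYGONS", lines)[1]
  if (is.na(ipoly)) stop("malformed VTK: no POLYGONS section")
  nf <- as.integer(strsplit(lines[ipoly], "\\s+")[[1]][2])
  fvals <- scan(text = paste(lines[(ipoly + 1):length(lines)], collapse = "\n"),
                n = 4 * nf, quiet = TRUE)
  fm <- matrix(fvals, ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3)) stop("malformed VTK: only triangles supported")
  lab <- integer(0)
  isc <- grep("^SCALARS label", lines)
  if (length(isc)) {
    lab <- as.integer(scan(text = paste(lines[(isc[1] + 2):length(lines)],
                                        collapse = "\n"),
                           n = nf, quiet = TRUE))
  }
  triSurfaceMesh(v, fm[, 2:4] + 1, faceLabels = lab)
}

writeVTKSurface <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  out <- c("# vtk DataFile Version 3.0", "atriflow surface", "ASCII",
           "DATASET POLYDATA",
           paste("POINTS", nrow(v), "float"),
           sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
           paste("POLYGONS", nrow(f), 4 * nrow(f)),
           sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  if (length(mesh@faceLabels) == nrow(f) && nrow(f) > 0) {
    out <- c(out, paste("CELL_DATA", nrow(f)), "SCALARS label int 1",
             "LOOKUP_TABLE default", paste(mesh@faceLabels))
  }
  writeLines(out, path)
}

# Tet mesh (+ optional nodal vector field) as legacy VTK unstructured grid.
writeVTKTetMesh <- function(mesh, path, pointVectors = NULL,
                            vectorName = "velocity") {
  v <- mesh@vertices; tt <- mesh@tets
  out <- c("# vtk DataFile Version 3.0", "atriflow volume", "ASCII",
           "DATASET UNSTRUCTURED_GRID",
           paste("POINTS", nrow(v), "float"),
           sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
           paste("CELLS", nrow(tt), 5 * nrow(tt)),
           sprintf("4 %d %d %d %d", tt[, 1] - 1L, tt[, 2] - 1L,
                   tt[, 3] - 1L, tt[, 4] - 1L),
           paste("CELL_TYPES", nrow(tt)),
           rep("10", nrow(tt)))
  if (!is.null(pointVectors)) {
    out <- c(out, paste("POINT_DATA", nrow(v)),
             paste("VECTORS", vectorName, "float"),
             sprintf("%.9g %.9g %.9g", pointVectors[, 1], pointVectors[, 2],
                     pointVectors[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}
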