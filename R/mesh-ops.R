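#' Construct a triangulated surface mesh
#'
#' @param vertices N x 3 numeric matrix (cm).
#' @param faces M x 3 integer matrix (1-based).
#' @param faceLabels optional integer vector per face (0 = wall).
#' @param labelNames optional named character vector mapping codes to names.
#' @param portTags optional named list of ordered boundary vertex loops.
#' @return a \linkS4class{TriSurfaceMesh}.
#' @export
triSurfaceMesh <- function(vertices, faces, faceLabels = integer(0),
                           labelNames = character(0), portTags = list()) {
  storage.mode(faces) <- "integer"
  new("TriSurfaceMesh", vertices = as.matrix(vertices), faces = faces,
      faceLabels = as.integer(faceLabels), labelNames = labelNames,
      portTags = portTags)
}

#' @rdname TriSurfaceMesh-class
#' @export
setMethod("vertices", "TriSurfaceMesh", function(x) x@vertices)
#' @rdname TriSurfaceMesh-class
#' @export
setMethod("faces", "TriSurfaceMesh", function(x) x@faces)
#' @rdname TriSurfaceMesh-class
#' @export
setMethod("nVertices", "TriSurfaceMesh", function(x) nrow(x@vertices))
#' @rdname TriSurfaceMesh-class
#' @export
setMethod("nFaces", "TriSurfaceMesh", function(x) nrow(x@faces))
#' @rdname TriSurfaceMesh-class
#' @export
setMethod("portTags", "TriSurfaceMesh", function(x) x@portTags)

setMethod("show", "TriSurfaceMesh", function(object) {
  cat("TriSurfaceMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces\n")
  if (length(object@portTags))
    cat("  ports:", paste(names(object@portTags), collapse = ", "), "\n")
  nb <- tryCatch(length(boundaryLoops(object)), error = function(e) NA)
  cat("  boundary loops:", nb, "\n")
})

setMethod("show", "TetMesh", function(object) {
  cat("TetMesh:", nrow(object@vertices), "vertices,",
      nrow(object@tets), "tets\n")
  cat("  patches:", paste(sort(unique(object@boundaryPatch)), collapse = ", "), "\n")
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline: %d points, L = %.3f cm, D = %.3f cm, chi = %.3f\n",
              nrow(object@points), object@L, object@D, object@L / object@D - 1))
})

setMethod("show", "LAAGeometryReport", function(object) {
  cat(sprintf(
    "LAA geometry: V = %.2f cm^3, As = %.2f cm^2, Ao = %.2f cm^2, Po = %.2f cm, L = %.2f cm, chi = %.3f\n",
    object@V, object@As, object@Ao, object@Po, object@L, object@chi))
})

#' @export
#' @describeIn LAAGeometryReport-class one-row data.frame with the Table-2
#'   style columns.
#' @param x an \code{LAAGeometryReport}.
#' @param row.names,optional,... passed on conventions of as.data.frame.
as.data.frame.LAAGeometryReport <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(V = x@V, A_s = x@As, A_o = x@Ao, P_o = x@Po, L = x@L,
             chi = x@chi, row.names = row.names)
}

faceAreas <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  0.5 * rowNorms(rowCross(v[f[, 2], , drop = FALSE] - a,
                          v[f[, 3], , drop = FALSE] - a))
}

faceNormals <- function(mesh, normalize = TRUE) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  n <- rowCross(v[f[, 2], , drop = FALSE] - a, v[f[, 3], , drop = FALSE] - a)
  if (normalize) normalizeRows(n) else n
}

faceCentroids <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' @rdname surfaceArea
#' @export
setMethod("surfaceArea", "TriSurfaceMesh", function(x) sum(faceAreas(x)))

#' @rdname enclosedVolume
#' @export
setMethod("enclosedVolume", "TriSurfaceMesh", function(x) {
  loops <- boundaryLoops(x)
  if (length(loops) > 0)
    stop("mesh is not closed: ", length(loops),
         " open boundary loop(s); cap ports before computing the volume")
  v <- x@vertices; f <- x@faces
  a <- v[f[, 1], , drop = FALSE]
  abs(sum(rowSums(rowCross(a, v[f[, 2], , drop = FALSE]) *
                  v[f[, 3], , drop = FALSE])) / 6)
})

# Directed boundary edges (as they appear in the face orientation).
boundaryEdges <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt > 2)) stop("non-manifold edge(s) detected")
  e[key %in% names(cnt)[cnt == 1], , drop = FALSE]
}

#' @rdname boundaryLoops
#' @export
setMethod("boundaryLoops", "TriSurfaceMesh", function(x) {
  be <- boundaryEdges(x)
  if (nrow(be) == 0) return(list())
  nxt <- integer(nrow(x@vertices))
  if (anyDuplicated(be[, 1]) > 0)
    stop("non-manifold boundary: a vertex starts two boundary edges")
  nxt[be[, 1]] <- be[, 2]
  used <- rep(FALSE, nrow(be))
  names(used) <- be[, 1]
  starts <- be[, 1]
  seen <- rep(FALSE, nrow(x@vertices))
  loops <- list()
  for (s in starts) {
    if (seen[s]) next
    loop <- integer(0)
    cur <- s
    repeat {
      loop <- c(loop, cur)
      seen[cur] <- TRUE
      cur <- nxt[cur]
      if (cur == 0) stop("open boundary chain: mesh boundary is not a set of closed loops")
      if (cur == s) break
      if (length(loop) > nrow(x@vertices)) stop("boundary walk failed to close")
    }
    loops[[length(loops) + 1]] <- loop
  }
  len <- vapply(loops, function(l) {
    p <- x@vertices[l, , drop = FALSE]
    arclength(rbind(p, p[1, ]))
  }, numeric(1))
  loops[order(len, decreasing = TRUE)]
})

# Vertex adjacency list (by mesh edges).
vertexAdjacency <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, c(2, 1)])
  spl <- split(e[, 2], e[, 1])
  adj <- vector("list", nrow(mesh@vertices))
  adj[as.integer(names(spl))] <- lapply(spl, unique)
  adj
}

# Face adjacency (shared-edge) as an edge list of face index pairs.
faceAdjacencyEdges <- function(mesh) {
  f <- mesh@faces
  m <- nrow(f)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(m), 3)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  o <- order(key)
  key <- key[o]; fid <- fid[o]
  same <- key[-1] == key[-length(key)]
  cbind(fid[c(same, FALSE)], fid[c(FALSE, same)])
}

#' Laplacian smoothing of a surface mesh
#'
#' Uniform-weight umbrella smoothing: each interior vertex moves a fraction
#' \code{relaxation} toward the mean of its neighbors per iteration.
#' Boundary-loop vertices are held fixed so open ports keep their rims.
#'
#' @param mesh a \linkS4class{TriSurfaceMesh}.
#' @param iterations number of smoothing sweeps (0 = identity).
#' @param relaxation step fraction in (0, 1].
#' @param fixed optional extra vertex indices to hold fixed.
#' @return the smoothed mesh (same connectivity).
#' @export
laplacianSmooth <- function(mesh, iterations = 10, relaxation = 0.5,
                            fixed = integer(0)) {
  stopifnot(iterations >= 0)
  if (iterations == 0) return(mesh)
  v <- mesh@vertices
  f <- mesh@faces
  be <- boundaryEdges(mesh)
  hold <- unique(c(as.integer(be), as.integer(fixed)))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, c(2, 1)])
  e <- unique(e)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(nrow(v), nrow(v)))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  for (it in seq_len(iterations)) {
    mean_nb <- as.matrix(A %*% v) / deg
    vnew <- v + relaxation * (mean_nb - v)
    vnew[hold, ] <- v[hold, ]
    v <- vnew
  }
  methods::initialize(mesh, vertices = v)
}

#' Cap the open ports of a surface mesh
#'
#' Each boundary loop is closed by a triangle fan from its barycenter,
#' oriented consistently with the surrounding surface. Cap faces inherit the
#' port label (one integer code per port, recorded in \code{labelNames});
#' original faces keep label 0 (\code{WALL}) unless already labeled.
#'
#' @param mesh a \linkS4class{TriSurfaceMesh} with tagged ports.
#' @param ports names of ports to cap; default all boundary loops. Loops not
#'   matching a tag are capped with names \code{CAP1}, \code{CAP2}, ...
#' @return a closed \linkS4class{TriSurfaceMesh} with labeled cap faces.
#' @export
capPorts <- function(mesh, ports = NULL) {
  loops <- boundaryLoops(mesh)
  if (length(loops) == 0) return(mesh)
  # match loops to port tags by vertex membership
  tagOf <- rep(NA_character_, length(loops))
  for (nm in names(mesh@portTags)) {
    tagged <- mesh@portTags[[nm]]
    for (i in seq_along(loops))
      if (length(intersect(loops[[i]], tagged)) > 0.5 * length(loops[[i]]))
        tagOf[i] <- nm
  }
  capn <- 0
  for (i in seq_along(loops)) if (is.na(tagOf[i])) {
    capn <- capn + 1
    tagOf[i] <- paste0("CAP", capn)
  }
  if (!is.null(ports)) {
    keep <- tagOf %in% ports
    loops <- loops[keep]; tagOf <- tagOf[keep]
  }
  v <- mesh@vertices
  f <- mesh@faces
  lab <- if (length(mesh@faceLabels)) mesh@faceLabels else rep(0L, nrow(f))
  labNames <- mesh@labelNames
  if (!"0" %in% names(labNames)) labNames <- c(labNames, "0" = "WALL")
  nextCode <- max(c(0L, suppressWarnings(as.integer(names(labNames)))), na.rm = TRUE) + 1L
  for (i in seq_along(loops)) {
    loop <- loops[[i]]
    bc <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, bc)
    ci <- nrow(v)
    nl <- length(loop)
    # boundary walk follows directed boundary edges u -> v; the cap triangle
    # (v, u, center) restores the closed orientation
    newf <- cbind(loop[c(2:nl, 1)], loop, rep(ci, nl))
    f <- rbind(f, newf)
    code <- nextCode; nextCode <- nextCode + 1L
    lab <- c(lab, rep(code, nl))
    labNames[as.character(code)] <- tagOf[i]
  }
  triSurfaceMesh(v, f, faceLabels = lab, labelNames = labNames,
                 portTags = mesh@portTags)
}

#' Apply a rigid (optionally scaled) transform to points or a mesh
#'
#' @param x an N x 3 matrix or a \linkS4class{TriSurfaceMesh}.
#' @param transform a \linkS4class{RigidTransform}.
#' @return the transformed object.
#' @export
applyTransform <- function(x, transform) {
  tr <- function(p) sweep(transform@scale * p %*% t(transform@rotation), 2,
                          -transform@translation)
  if (is(x, "TriSurfaceMesh")) methods::initialize(x, vertices = tr(x@vertices))
  else tr(as.matrix(x))
}

# Subset of faces as a standalone mesh with renumbered vertices.
# Returns the submesh plus the original vertex indices (vmap).
subsetFaces <- function(mesh, faceIdx) {
  f <- mesh@faces[faceIdx, , drop = FALSE]
  used <- sort(unique(as.integer(f)))
  remap <- integer(nrow(mesh@vertices))
  remap[used] <- seq_along(used)
  f2 <- matrix(remap[f], ncol = 3)
  lab <- if (length(mesh@faceLabels)) mesh@faceLabels[faceIdx] else integer(0)
  list(mesh = triSurfaceMesh(mesh@vertices[used, , drop = FALSE], f2,
                             faceLabels = lab, labelNames = mesh@labelNames),
       vmap = used)
}
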