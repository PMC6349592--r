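# LAA geometric descriptors: volume, lateral surface area, orifice area and
# perimeter, centerline length and tortuosity (chi = L/D - 1).

#' Compute the lumen centerline of an appendage
#'
#' The centerline runs from the ostium-rim barycenter to the apex (the
#' surface point at maximal multi-source geodesic distance from the rim).
#' It is the shortest path on a uniform interior point lattice with edge
#' weights \code{length / clearance} (clearance = distance to the wall), so
#' the path favors the lumen middle; the polyline is lightly smoothed and
#' reparameterized by arclength.
#'
#' @param laa open appendage mesh with an \code{OSTIUM} boundary loop.
#' @param gridSpacing lattice spacing (cm); default a fifth of the ostium
#'   radius, clamped to [0.04, 0.12] cm.
#' @return a \linkS4class{Centerline}.
#' @export
computeCenterline <- function(laa, gridSpacing = NULL) {
  loop <- laa@portTags$OSTIUM
  if (is.null(loop)) stop("appendage must carry an OSTIUM port tag")
  closed <- capPorts(laa)
  if (length(boundaryLoops(closed)) != 0)
    stop("appendage is not watertight after capping")
  rim <- laa@vertices[loop, , drop = FALSE]
  bc <- colMeans(rim)
  rOst <- mean(rowNorms(sweep(rim, 2, bc)))
  if (is.null(gridSpacing))
    gridSpacing <- min(max(rOst / 5, 0.04), 0.12)
  h <- gridSpacing

  v <- closed@vertices
  lo <- apply(v, 2, min) - h / 2
  hi <- apply(v, 2, max) + h / 2
  nx <- pmax(ceiling((hi - lo) / h), 2)
  gx <- lapply(1:3, function(k) lo[k] + h * (0:(nx[k])))
  grid <- as.matrix(expand.grid(x = gx[[1]], y = gx[[2]], z = gx[[3]]))
  dims <- nx + 1
  inside <- cpp_points_in_mesh(v, closed@faces, grid,
                               c(0.57731, 0.57718, 0.57760), 1e-9) == 1
  if (sum(inside) < 8) stop("lumen too small for the centerline lattice")
  gIdx <- which(inside)
  pts <- grid[gIdx, , drop = FALSE]
  clr <- cpp_closest_points(v, closed@faces, pts)$dist
  id <- integer(nrow(grid)); id[gIdx] <- seq_along(gIdx)

  # 26-neighborhood lattice edges among inside points
  arr <- arrayInd(gIdx, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  eFrom <- integer(0); eTo <- integer(0); eW <- numeric(0)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(arr, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- (nb[ok, 3] - 1) * dims[1] * dims[2] + (nb[ok, 2] - 1) * dims[1] + nb[ok, 1]
    tid <- id[lin]
    src <- which(ok)[tid > 0]
    dst <- tid[tid > 0]
    len <- h * vnorm(offs[o, ])
    wgt <- len / (0.5 * (clr[src] + clr[dst]) + 0.05 * h)
    eFrom <- c(eFrom, src); eTo <- c(eTo, dst); eW <- c(eW, wgt)
  }
  g <- igraph::graph_from_edgelist(cbind(eFrom, eTo), directed = FALSE)
  if (igraph::vcount(g) < length(gIdx))
    g <- igraph::add_vertices(g, length(gIdx) - igraph::vcount(g))

  # apex: surface vertex farthest (geodesically) from the rim
  sf <- laa@faces
  se <- unique(rbind(sf[, 1:2], sf[, 2:3], sf[, c(3, 1)]))
  sg <- igraph::graph_from_edgelist(se, directed = FALSE)
  if (igraph::vcount(sg) < nrow(laa@vertices))
    sg <- igraph::add_vertices(sg, nrow(laa@vertices) - igraph::vcount(sg))
  sw <- rowNorms(laa@vertices[se[, 1], , drop = FALSE] -
                   laa@vertices[se[, 2], , drop = FALSE])
  dsurf <- igraph::distances(sg, v = loop, weights = sw)
  apex <- laa@vertices[which.max(apply(dsurf, 2, min)), ]

  srcNode <- which.min(rowNorms(sweep(pts, 2, bc)))
  dstNode <- which.min(rowNorms(sweep(pts, 2, apex)))
  sp <- igraph::shortest_paths(g, from = srcNode, to = dstNode, weights = eW)
  nodePath <- as.integer(sp$vpath[[1]])
  if (length(nodePath) < 1 || nodePath[length(nodePath)] != dstNode)
    stop("no interior path from ostium to apex; refine gridSpacing")
  path <- rbind(bc, pts[nodePath, , drop = FALSE], apex)
  # light smoothing, endpoints pinned
  for (pass in 1:4) {
    if (nrow(path) < 3) break
    mid <- (path[-c(1, 2), , drop = FALSE] + path[-c(nrow(path) - 1, nrow(path)), , drop = FALSE]) / 2
    path[2:(nrow(path) - 1), ] <- 0.5 * path[2:(nrow(path) - 1), , drop = FALSE] + 0.5 * mid
  }
  # uniform arclength reparameterization
  L0 <- arclength(path)
  path <- polylineAt(path, seq(0, L0, length.out = max(20, nrow(path))))
  new("Centerline", points = path, L = arclength(path),
      D = vnorm(path[nrow(path), ] - path[1, ]))
}

#' @rdname tortuosity
#' @export
setMethod("tortuosity", "Centerline", function(x) {
  if (x@D <= 0) stop("endpoint distance is zero (closed loop?)")
  x@L / x@D - 1
})

#' Orifice area and perimeter of a rim loop
#'
#' The perimeter is the closed polyline length; the area is the polygon
#' area after projection onto the least-squares plane of the rim (shoelace
#' formula). A self-intersecting projection falls back to the cross-product
#' sum about the barycenter, with a message.
#'
#' @param rim ordered n x 3 rim loop, or a mesh with an \code{OSTIUM} tag.
#' @return list with \code{Ao} (cm^2) and \code{Po} (cm).
#' @export
orificeMetrics <- function(rim) {
  if (is(rim, "TriSurfaceMesh")) {
    loop <- rim@portTags$OSTIUM
    if (is.null(loop)) stop("mesh has no OSTIUM tag")
    rim <- rim@vertices[loop, , drop = FALSE]
  }
  rim <- as.matrix(rim)
  n <- nrow(rim)
  if (n < 3) stop("rim needs at least 3 points")
  Po <- arclength(rbind(rim, rim[1, ]))
  ctr <- colMeans(rim)
  X <- sweep(rim, 2, ctr)
  pl <- svd(X)$v
  uv <- X %*% pl[, 1:2]
  if (polygonSelfIntersects(uv)) {
    message("rim projection self-intersects; using barycentric cross-product area")
    nxt <- c(2:n, 1)
    Ao <- 0.5 * vnorm(colSums(rowCross(X, X[nxt, , drop = FALSE])))
  } else {
    nxt <- c(2:n, 1)
    Ao <- abs(sum(uv[, 1] * uv[nxt, 2] - uv[nxt, 1] * uv[, 2]) / 2)
  }
  list(Ao = Ao, Po = Po)
}

polygonSelfIntersects <- function(uv) {
  n <- nrow(uv)
  nxt <- c(2:n, 1)
  segInt <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    d1 * d2 < 0 && d3 * d4 < 0
  }
  for (i in seq_len(n - 2)) for (j in (i + 2):n) {
    if (i == 1 && j == n) next
    if (segInt(uv[i, ], uv[nxt[i], ], uv[j, ], uv[nxt[j], ])) return(TRUE)
  }
  FALSE
}

#' Assemble the geometric descriptor report of an appendage
#'
#' Volume is the enclosed volume after capping the ostium; the lateral
#' surface area excludes the ostium cap (the orifice is an aperture, not
#' wall); orifice metrics come from the rim loop; length and tortuosity from
#' the computed centerline.
#'
#' @param laa open appendage mesh with an \code{OSTIUM} tag.
#' @param gridSpacing passed to \code{\link{computeCenterline}}.
#' @return an \linkS4class{LAAGeometryReport}.
#' @export
geometryReport <- function(laa, gridSpacing = NULL) {
  closed <- capPorts(laa)
  V <- enclosedVolume(closed)
  As <- surfaceArea(laa) # cap excluded: laa is the open wall only
  om <- orificeMetrics(laa)
  cl <- computeCenterline(laa, gridSpacing = gridSpacing)
  new("LAAGeometryReport", V = V, As = As, Ao = om$Ao, Po = om$Po,
      L = cl@L, chi = tortuosity(cl))
}
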