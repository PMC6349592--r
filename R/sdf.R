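# Shape diameter function (SDF) segmentation: per-face local diameter by
# interior cone ray casting, semantic clustering of the field, and automatic
# LAA isolation.

#' Compute the shape diameter function of a closed surface mesh
#'
#' For each face, a cone of \code{nRays} rays is cast from the face centroid
#' into the mesh interior (opposite the outward normal). Intersections whose
#' surface normal points the same way as the source normal are discarded as
#' false hits; of the remaining ray lengths only those within one standard
#' deviation of the median are kept, and the SDF value is their weighted
#' average with weights inverse to the ray's angle from the cone axis.
#'
#' The cone sampling frame is built from the face's own geometry, so the
#' field is exactly pose-invariant under rigid transforms (same seed), and
#' scales linearly under uniform scaling.
#'
#' @param mesh a closed, outward-oriented \linkS4class{TriSurfaceMesh}.
#' @param coneHalfAngle cone half angle in radians (default 60 degrees);
#'   0 degenerates to the single antipodal ray.
#' @param nRays rays per face (>= 4).
#' @param seed RNG seed for the (shared) cone sample pattern.
#' @return an \linkS4class{SDFField}.
#' @export
computeSDF <- function(mesh, coneHalfAngle = pi / 3, nRays = 30L, seed = 1L) {
  stopifnot(nRays >= 4, coneHalfAngle >= 0, coneHalfAngle < pi / 2 + 1e-9)
  if (length(boundaryLoops(mesh)) > 0)
    stop("SDF requires a closed mesh; cap open ports first")
  v <- mesh@vertices; f <- mesh@faces
  nf <- nrow(f)
  ctr <- faceCentroids(mesh)
  nrm <- faceNormals(mesh)
  scale <- vnorm(apply(v, 2, max) - apply(v, 2, min))
  # one shared cone pattern (area-uniform in the cap), rotated per face
  pat <- withSeed(seed, {
    u <- runif(nRays); phi <- runif(nRays, 0, 2 * pi)
    theta <- acos(1 - u * (1 - cos(coneHalfAngle)))
    cbind(theta, phi)
  })
  w <- 1 / pmax(pat[, 1], max(coneHalfAngle, 1e-6) / 30)
  e0 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  vals <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    n <- nrm[i, ]
    e1 <- e0[i, ] - sum(e0[i, ] * n) * n
    e1 <- e1 / vnorm(e1)
    e2 <- pracma_cross(n, e1)
    ax <- -n
    dirs <- outer(cos(pat[, 1]), ax) +
      sin(pat[, 1]) * (outer(cos(pat[, 2]), e1) + outer(sin(pat[, 2]), e2))
    hits <- cpp_ray_first_hits(v, f, ctr[i, ], dirs, i - 1L, n, TRUE,
                               1e-7 * scale)
    ok <- is.finite(hits)
    if (!any(ok)) next
    len <- hits[ok]
    ww <- w[ok]
    med <- median(len)
    s <- if (length(len) > 1) sd(len) else 0
    keep <- abs(len - med) <= s + 1e-12
    vals[i] <- sum(len[keep] * ww[keep]) / sum(ww[keep])
  }
  if (anyNA(vals)) {
    # faces with no surviving ray inherit the nearest labeled neighbor
    bad <- which(is.na(vals))
    message(length(bad), " face(s) had no surviving SDF ray; filled from neighbors")
    adj <- faceAdjacencyEdges(mesh)
    g <- igraph::graph_from_edgelist(adj, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nf - igraph::vcount(g)))
    for (b in bad) {
      d <- igraph::distances(g, v = b)
      cand <- order(d)
      cand <- cand[!is.na(vals[cand])]
      vals[b] <- vals[cand[1]]
    }
  }
  new("SDFField", values = vals, coneHalfAngle = coneHalfAngle,
      nRays = as.integer(nRays), seed = as.integer(seed))
}

#' Cluster an SDF field into edge-connected semantic regions
#'
#' One-dimensional k-means on log-SDF values seeds the labels
#' (deterministically, from value quantiles); iterated majority voting over
#' face-adjacency neighborhoods regularizes the boundaries; each label is
#' finally split into edge-connected components so every region is connected.
#'
#' @param sdf an \linkS4class{SDFField}.
#' @param mesh the mesh the field was computed on.
#' @param kClusters number of SDF clusters (>= 1).
#' @param spatialWeight weight in [0, 1] of the neighborhood vote against
#'   the face's own label (0 = no regularization).
#' @param maxIter maximum voting sweeps.
#' @param mergeTol adjacent regions whose mean log-SDF differs by less than
#'   this are merged after splitting: statistically insignificant splits of
#'   a near-uniform field collapse back into one region.
#' @return a \linkS4class{RegionLabels}.
#' @export
clusterRegions <- function(sdf, mesh, kClusters = 4L, spatialWeight = 0.5,
                           maxIter = 20L, mergeTol = 0.3) {
  stopifnot(kClusters >= 1, spatialWeight >= 0, spatialWeight <= 1)
  x <- log(sdf@values)
  nf <- length(x)
  if (kClusters > length(unique(signif(x, 12))))
    stop("kClusters exceeds the number of distinct SDF values")
  if (kClusters == 1) {
    lab <- rep(1L, nf)
  } else {
    centers <- unique(as.numeric(
      stats::quantile(x, probs = seq(0.05, 0.95, length.out = kClusters))))
    km <- suppressWarnings(kmeans(x, centers = matrix(centers), iter.max = 100))
    ord <- order(km$centers)
    lab <- match(km$cluster, ord)
  }
  adj <- faceAdjacencyEdges(mesh)
  A <- Matrix::sparseMatrix(i = c(adj[, 1], adj[, 2]),
                            j = c(adj[, 2], adj[, 1]), x = 1,
                            dims = c(nf, nf))
  deg <- pmax(Matrix::rowSums(A), 1)
  if (spatialWeight > 0 && kClusters > 1) {
    # neighbor votes are counts; the face's own (data) label carries weight
    # (1 - w), so w = 0 disables smoothing and larger w absorbs islands
    for (it in seq_len(maxIter)) {
      score <- sapply(seq_len(kClusters), function(l)
        spatialWeight * as.numeric(A %*% (lab == l)) +
          (1 - spatialWeight) * (lab == l))
      newlab <- max.col(score, ties.method = "first")
      if (all(newlab == lab)) break
      lab <- newlab
    }
  }
  # split labels into edge-connected components
  same <- lab[adj[, 1]] == lab[adj[, 2]]
  g <- igraph::graph_from_edgelist(adj[same, , drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < nf) g <- igraph::add_vertices(g, nf - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  # merge adjacent regions that the field does not actually separate
  if (mergeTol > 0) {
    repeat {
      means <- tapply(x, comp, mean)
      ra <- unique(cbind(pmin(comp[adj[, 1]], comp[adj[, 2]]),
                         pmax(comp[adj[, 1]], comp[adj[, 2]])))
      ra <- ra[ra[, 1] != ra[, 2], , drop = FALSE]
      if (nrow(ra) == 0) break
      dm <- abs(means[as.character(ra[, 1])] - means[as.character(ra[, 2])])
      if (min(dm) >= mergeTol) break
      pair <- ra[which.min(dm), ]
      comp[comp == pair[2]] <- pair[1]
    }
    comp <- match(comp, sort(unique(comp)))
  }
  new("RegionLabels", labels = as.integer(comp),
      chamberId = modeInt(as.integer(comp)))
}

#' Identify the LAA region among clustered surface regions
#'
#' The atrial chamber is the modal region; regions whose faces touch a
#' tagged PV or MV port rim are merged into the chamber. The LAA is the
#' region containing the hint point when given, otherwise the largest
#' remaining region adjacent to the chamber. The returned face set is
#' regularized so the cut against the chamber is a single simple loop.
#'
#' @param labels a \linkS4class{RegionLabels}.
#' @param mesh the labeled mesh (with port tags, unless a hint is given).
#' @param hint optional length-3 point near the appendage.
#' @param minAreaFrac smallest believable appendage area, as a fraction of
#'   the total surface (guards against picking a sliver transition region).
#' @return integer vector of LAA face indices.
#' @export
identifyLAA <- function(labels, mesh, hint = NULL, minAreaFrac = 0.02) {
  lab <- labels@labels
  nf <- nrow(mesh@faces)
  stopifnot(length(lab) == nf)
  chamberSet <- labels@chamberId
  portVerts <- unlist(mesh@portTags[grepl("^(PV|MV)", names(mesh@portTags))])
  if (length(portVerts)) {
    touches <- which(matrix(mesh@faces %in% portVerts, ncol = 3) %*% rep(1, 3) > 0)
    chamberSet <- union(chamberSet, unique(lab[touches]))
  }
  adj <- faceAdjacencyEdges(mesh)
  inCh <- lab %in% chamberSet
  # appendage candidates: connected unions of non-chamber regions (the
  # appendage body plus its transition ring) that touch the chamber
  sameOut <- !inCh[adj[, 1]] & !inCh[adj[, 2]]
  g <- igraph::graph_from_edgelist(adj[sameOut, , drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < nf) g <- igraph::add_vertices(g, nf - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  comp[inCh] <- NA
  touchCh <- unique(c(comp[adj[, 1]][inCh[adj[, 2]]],
                      comp[adj[, 2]][inCh[adj[, 1]]]))
  touchCh <- touchCh[!is.na(touchCh)]
  areas <- faceAreas(mesh)
  if (!is.null(hint)) {
    ctr <- faceCentroids(mesh)
    hf <- which.min(rowNorms(sweep(ctr, 2, hint)))
    if (inCh[hf])
      stop("hint resolves to the chamber region, not an appendage")
    faceSet <- which(!is.na(comp) & comp == comp[hf])
  } else {
    cand <- touchCh[vapply(touchCh, function(cc)
      sum(areas[which(!is.na(comp) & comp == cc)]), numeric(1)) >=
        minAreaFrac * sum(areas)]
    if (length(cand) == 0) stop("no appendage candidate")
    best <- cand[which.max(vapply(cand, function(cc)
      sum(areas[which(!is.na(comp) & comp == cc)]), numeric(1)))]
    faceSet <- which(!is.na(comp) & comp == best)
  }
  if (length(faceSet) == 0) stop("no appendage candidate")
  regularizeCut(mesh, faceSet, adj)
}

# Make the LAA/chamber cut a single simple loop: keep the largest connected
# component, absorb complement islands, and grow over pinch vertices.
regularizeCut <- function(mesh, faceSet, adj = faceAdjacencyEdges(mesh)) {
  nf <- nrow(mesh@faces)
  inSet <- rep(FALSE, nf); inSet[faceSet] <- TRUE
  sameIn <- inSet[adj[, 1]] & inSet[adj[, 2]]
  g <- igraph::graph_from_edgelist(adj[sameIn, , drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < nf) g <- igraph::add_vertices(g, nf - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  compSizes <- table(comp[inSet])
  keepComp <- as.integer(names(compSizes)[which.max(compSizes)])
  inSet <- inSet & comp == keepComp
  # absorb complement islands (complement components that are not the chamber)
  sameOut <- !inSet[adj[, 1]] & !inSet[adj[, 2]]
  g2 <- igraph::graph_from_edgelist(adj[sameOut, , drop = FALSE], directed = FALSE)
  if (igraph::vcount(g2) < nf) g2 <- igraph::add_vertices(g2, nf - igraph::vcount(g2))
  comp2 <- igraph::components(g2)$membership
  outSizes <- table(comp2[!inSet])
  mainOut <- as.integer(names(outSizes)[which.max(outSizes)])
  inSet[!inSet & comp2 != mainOut] <- TRUE
  # grow over pinch vertices until the cut is simple
  f <- mesh@faces
  for (it in 1:10) {
    cutE <- cutEdges(f, inSet)
    if (nrow(cutE) == 0) break
    cnt <- table(as.integer(cutE))
    pinch <- as.integer(names(cnt)[cnt > 2])
    if (length(pinch) == 0) break
    addF <- which(!inSet & matrix(f %in% pinch, ncol = 3) %*% rep(1, 3) > 0)
    if (length(addF) == 0) break
    inSet[addF] <- TRUE
  }
  which(inSet)
}

# Edges between in-set and out-set faces (vertex index pairs).
cutEdges <- function(f, inSet) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nrow(f)), 3)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  o <- order(key)
  key <- key[o]; fid <- fid[o]; e <- e[o, , drop = FALSE]
  i1 <- which(c(key[-1] == key[-length(key)], FALSE))
  cut <- xor(inSet[fid[i1]], inSet[fid[i1 + 1]])
  e[i1[cut], , drop = FALSE]
}

#' Extract a face subset as a standalone mesh, plus the remainder
#'
#' The face set must be edge-connected and cut the mesh along a single
#' simple loop; that loop becomes the \code{OSTIUM} tag of both parts.
#'
#' @param mesh a \linkS4class{TriSurfaceMesh}.
#' @param faceSet integer face indices (the appendage).
#' @return list with \code{laa} and \code{remainder} meshes.
#' @export
extractSubmesh <- function(mesh, faceSet) {
  nf <- nrow(mesh@faces)
  stopifnot(all(faceSet >= 1 & faceSet <= nf))
  adj <- faceAdjacencyEdges(mesh)
  inSet <- rep(FALSE, nf); inSet[faceSet] <- TRUE
  sameIn <- inSet[adj[, 1]] & inSet[adj[, 2]]
  g <- igraph::graph_from_edgelist(adj[sameIn, , drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < nf) g <- igraph::add_vertices(g, nf - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  if (length(unique(comp[faceSet])) > 1)
    stop("face set is not edge-connected")
  nOrigLoops <- length(boundaryLoops(mesh))
  sub <- subsetFaces(mesh, faceSet)
  laa <- sub$mesh
  laaLoops <- boundaryLoops(laa)
  if (length(laaLoops) != 1)
    stop("non-simple cut: extracted part has ", length(laaLoops),
         " boundary loops (expected 1)")
  laa@portTags <- list(OSTIUM = laaLoops[[1]])
  rem <- subsetFaces(mesh, setdiff(seq_len(nf), faceSet))
  remainder <- rem$mesh
  # remap surviving port tags, and tag the new cut loop as OSTIUM
  tags <- lapply(mesh@portTags, function(tg) {
    m <- match(tg, rem$vmap)
    if (anyNA(m)) NULL else m
  })
  tags <- tags[!vapply(tags, is.null, logical(1))]
  cutVertsOrig <- sub$vmap[laaLoops[[1]]]
  remLoops <- boundaryLoops(remainder)
  isCut <- vapply(remLoops, function(l)
    all(rem$vmap[l] %in% cutVertsOrig), logical(1))
  if (sum(isCut) != 1)
    stop("non-simple cut: remainder does not expose a single matching loop")
  tags$OSTIUM <- remLoops[[which(isCut)]]
  remainder@portTags <- tags
  list(laa = laa, remainder = remainder)
}
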