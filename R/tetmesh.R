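# Volume meshing by background-grid Kuhn subdivision: interior lattice cubes
# are split into six conforming tetrahedra and the outer vertex layer is
# snapped onto the input surface. Robust for the smooth watertight composites
# produced by the grafting pipeline; not a general-purpose mesher.

#' Tetrahedralize a watertight labeled surface
#'
#' @param surface closed \linkS4class{TriSurfaceMesh} whose faces carry
#'   labels (0/WALL plus one code per capped port; see
#'   \code{\link{capPorts}}).
#' @param maxCellSize target lattice edge length h (cm); tets have edges
#'   h to h*sqrt(3).
#' @param snap move outer-layer vertices onto the surface (recommended);
#'   snapping is rolled back locally where it would invert a tetrahedron.
#' @return a \linkS4class{TetMesh} whose boundary faces are labeled with the
#'   patch names of the nearest input faces.
#' @export
tetrahedralize <- function(surface, maxCellSize, snap = TRUE) {
  loops <- boundaryLoops(surface)
  if (length(loops) > 0)
    stop("surface is not watertight: ", length(loops),
         " open boundary loop(s)")
  h <- maxCellSize
  v <- surface@vertices
  lo <- apply(v, 2, min)
  hi <- apply(v, 2, max)
  n <- pmax(ceiling((hi - lo) / h - 1e-9), 1)
  hs <- (hi - lo) / n # per-axis spacing, aligned to the bounding box
  dims <- n + 1
  gx <- lapply(1:3, function(k) lo[k] + hs[k] * (0:n[k]))
  grid <- as.matrix(expand.grid(x = gx[[1]], y = gx[[2]], z = gx[[3]]))
  diag3 <- vnorm(hi - lo)
  inside <- cpp_points_in_mesh(v, surface@faces, grid,
                               c(0.57731, 0.57718, 0.57760),
                               1e-9 * diag3) == 1
  # dilate by half a cell: outside lattice points closer than h/2 to the
  # surface join the domain, so the snapped boundary interpolates the true
  # surface (O(h^2) volume error instead of a one-sided staircase deficit)
  insArr <- array(inside, dims)
  nbIn <- array(FALSE, dims)
  d1 <- dims[1]; d2 <- dims[2]; d3 <- dims[3]
  nbIn[-1, , ] <- nbIn[-1, , ] | insArr[-d1, , ]
  nbIn[-d1, , ] <- nbIn[-d1, , ] | insArr[-1, , ]
  nbIn[, -1, ] <- nbIn[, -1, ] | insArr[, -d2, ]
  nbIn[, -d2, ] <- nbIn[, -d2, ] | insArr[, -1, ]
  nbIn[, , -1] <- nbIn[, , -1] | insArr[, , -d3]
  nbIn[, , -d3] <- nbIn[, , -d3] | insArr[, , -1]
  cand <- which(!inside & as.vector(nbIn))
  if (length(cand)) {
    dOut <- cpp_closest_points(v, surface@faces, grid[cand, , drop = FALSE])$dist
    inside[cand[dOut < 0.5 * min(hs)]] <- TRUE
  }
  lin <- function(i, j, k) (k - 1) * dims[1] * dims[2] + (j - 1) * dims[1] + i
  # cubes whose 8 corners are all inside
  cg <- as.matrix(expand.grid(i = 1:n[1], j = 1:n[2], k = 1:n[3]))
  corner <- function(di, dj, dk) lin(cg[, 1] + di, cg[, 2] + dj, cg[, 3] + dk)
  c000 <- corner(0, 0, 0); c100 <- corner(1, 0, 0)
  c010 <- corner(0, 1, 0); c110 <- corner(1, 1, 0)
  c001 <- corner(0, 0, 1); c101 <- corner(1, 0, 1)
  c011 <- corner(0, 1, 1); c111 <- corner(1, 1, 1)
  allIn <- inside[c000] & inside[c100] & inside[c010] & inside[c110] &
    inside[c001] & inside[c101] & inside[c011] & inside[c111]
  if (!any(allIn))
    stop("meshing failure: no lattice cube fits inside the surface; reduce maxCellSize")
  # Kuhn subdivision along the main diagonal c000 -> c111 (conforming across cubes)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  cid <- list(c100, c010, c001) # +x, +y, +z single steps from c000
  cid2 <- list(`12` = c110, `13` = c101, `21` = c110, `23` = c011,
               `31` = c101, `32` = c011)
  tets <- vector("list", 6)
  for (p in seq_len(6)) {
    a <- cid[[perms[p, 1]]][allIn]
    key <- paste0(perms[p, 1], perms[p, 2])
    b <- cid2[[key]][allIn]
    tets[[p]] <- cbind(c000[allIn], a, b, c111[allIn])
  }
  tt <- do.call(rbind, tets)
  used <- sort(unique(as.integer(tt)))
  remap <- integer(nrow(grid)); remap[used] <- seq_along(used)
  tt <- matrix(remap[tt], ncol = 4)
  vt <- grid[used, , drop = FALSE]
  # orient positively
  vol <- tetVolumes(vt, tt)
  flip <- vol < 0
  if (any(flip)) tt[flip, c(3, 4)] <- tt[flip, c(4, 3)]

  # drop disconnected pockets (thin features can strand isolated cubes)
  eg <- rbind(tt[, c(1, 2)], tt[, c(1, 3)], tt[, c(1, 4)],
              tt[, c(2, 3)], tt[, c(2, 4)], tt[, c(3, 4)])
  g <- igraph::graph_from_edgelist(eg, directed = FALSE)
  comp <- igraph::components(g)$membership
  main <- modeInt(comp[tt[, 1]])
  keepT <- comp[tt[, 1]] == main
  if (!all(keepT)) {
    tt <- tt[keepT, , drop = FALSE]
    usedv <- sort(unique(as.integer(tt)))
    remap2 <- integer(nrow(vt)); remap2[usedv] <- seq_along(usedv)
    tt <- matrix(remap2[tt], ncol = 4)
    vt <- vt[usedv, , drop = FALSE]
  }

  bf <- tetBoundaryFaces(tt)
  if (snap) {
    bvs <- sort(unique(as.integer(bf)))
    cp <- cpp_closest_points(v, surface@faces, vt[bvs, , drop = FALSE])
    d <- cp$dist
    move <- d <= 1.5 * max(hs)
    target <- vt[bvs, , drop = FALSE]
    target[move, ] <- cp$point[move, , drop = FALSE]
    # per-vertex snap with rollback where a tet would invert
    fac <- rep(1, length(bvs))
    for (round in 1:8) {
      vtry <- vt
      vtry[bvs, ] <- vt[bvs, , drop = FALSE] * (1 - fac) + target * fac
      vol <- tetVolumes(vtry, tt)
      # refuse slivers: they would poison the lumped-mass projection
      bad <- which(vol <= 0.02 * prod(hs))
      if (length(bad) == 0) { vt <- vtry; break }
      badV <- unique(as.integer(tt[bad, ]))
      fac[bvs %in% badV] <- fac[bvs %in% badV] * 0.5
      if (round == 8) {
        fac[bvs %in% badV] <- 0
        vtry <- vt
        vtry[bvs, ] <- vt[bvs, , drop = FALSE] * (1 - fac) + target * fac
        if (any(tetVolumes(vtry, tt) <= 0))
          stop("meshing failure: could not snap boundary without inverting tets near ",
               paste(round(colMeans(vt[badV, , drop = FALSE]), 2), collapse = ", "))
        vt <- vtry
      }
    }
  }
  # patch labels: nearest input face decides
  fctr <- (vt[bf[, 1], , drop = FALSE] + vt[bf[, 2], , drop = FALSE] +
             vt[bf[, 3], , drop = FALSE]) / 3
  nearf <- cpp_closest_points(v, surface@faces, fctr)$face
  labs <- if (length(surface@faceLabels)) surface@faceLabels[nearf]
          else rep(0L, length(nearf))
  labNames <- surface@labelNames
  if (!"0" %in% names(labNames)) labNames["0"] <- "WALL"
  patch <- unname(labNames[as.character(labs)])
  patch[is.na(patch)] <- "WALL"
  # staircase faces tangential to a port cap belong to the wall: keep the
  # port label only where the boundary face is roughly parallel to the cap,
  # so port areas and plug scalings stay faithful
  a2 <- vt[bf[, 1], , drop = FALSE]
  bfn <- normalizeRows(rowCross(vt[bf[, 2], , drop = FALSE] - a2,
                                vt[bf[, 3], , drop = FALSE] - a2))
  inN <- faceNormals(surface)
  for (code in setdiff(unique(labs), 0L)) {
    pn <- colMeans(inN[surface@faceLabels == code, , drop = FALSE])
    pn <- pn / max(vnorm(pn), 1e-300)
    sel <- which(patch == labNames[as.character(code)])
    offAxis <- sel[as.numeric(bfn[sel, , drop = FALSE] %*% pn) < 0.6]
    patch[offAxis] <- "WALL"
    if (!any(patch == labNames[as.character(code)]))
      stop("meshing failure: port ", labNames[as.character(code)],
           " unresolved at this cell size")
  }
  new("TetMesh", vertices = vt, tets = tt, boundaryFaces = bf,
      boundaryPatch = patch)
}

tetVolumes <- function(v, tt) {
  a <- v[tt[, 1], , drop = FALSE]
  rowSums(rowCross(v[tt[, 2], , drop = FALSE] - a,
                   v[tt[, 3], , drop = FALSE] - a) *
            (v[tt[, 4], , drop = FALSE] - a)) / 6
}

# Outward-oriented boundary triangles of a positively oriented tet mesh.
tetBoundaryFaces <- function(tt) {
  # local faces with outward orientation for a positive tet (1,2,3,4)
  fl <- rbind(tt[, c(1, 3, 2)], tt[, c(1, 2, 4)], tt[, c(2, 3, 4)],
              tt[, c(1, 4, 3)])
  key <- paste(pmin(fl[, 1], pmin(fl[, 2], fl[, 3])),
               fl[, 1] + fl[, 2] + fl[, 3],
               pmax(fl[, 1], pmax(fl[, 2], fl[, 3])))
  cnt <- table(key)
  ext <- key %in% names(cnt)[cnt == 1]
  fl[ext, , drop = FALSE]
}
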