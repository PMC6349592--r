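# P1 finite element operators on a tetrahedral mesh: lumped mass, scalar
# stiffness, per-cell gradient matrices and boundary patch quadrature.
# All assembly is vectorized over cells.

femOperators <- function(mesh) {
  v <- mesh@vertices
  tt <- mesh@tets
  nc <- nrow(tt); nv <- nrow(v)
  p1 <- v[tt[, 1], , drop = FALSE]; p2 <- v[tt[, 2], , drop = FALSE]
  p3 <- v[tt[, 3], , drop = FALSE]; p4 <- v[tt[, 4], , drop = FALSE]
  vol6 <- rowSums(rowCross(p2 - p1, p3 - p1) * (p4 - p1))
  vol <- vol6 / 6
  if (any(vol <= 0)) stop("negative tet volume in FEM assembly")
  g1 <- rowCross(p4 - p2, p3 - p2) / vol6
  g2 <- rowCross(p3 - p1, p4 - p1) / vol6
  g3 <- rowCross(p4 - p1, p2 - p1) / vol6
  g4 <- rowCross(p2 - p1, p3 - p1) / vol6
  G <- list(g1, g2, g3, g4)
  cells <- seq_len(nc)
  mkG <- function(comp) Matrix::sparseMatrix(
    i = rep(cells, 4), j = as.integer(tt),
    x = c(g1[, comp], g2[, comp], g3[, comp], g4[, comp]),
    dims = c(nc, nv))
  Gx <- mkG(1); Gy <- mkG(2); Gz <- mkG(3)
  # lumped mass and volume scatter
  mL <- as.numeric(Matrix::sparseMatrix(
    i = as.integer(tt), j = rep(1L, 4L * nc), x = rep(vol / 4, 4),
    dims = c(nv, 1)))
  Sc <- Matrix::sparseMatrix(i = as.integer(tt), j = rep(cells, 4),
                             x = rep(vol / 4, 4), dims = c(nv, nc))
  # scalar stiffness K_ij = sum_c vol_c grad_i . grad_j
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (a in 1:4) for (b in 1:4) {
    ii <- c(ii, tt[, a]); jj <- c(jj, tt[, b])
    xx <- c(xx, vol * rowSums(G[[a]] * G[[b]]))
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
  Av <- Matrix::sparseMatrix(i = rep(cells, 4), j = as.integer(tt),
                             x = rep(0.25, 4L * nc), dims = c(nc, nv))
  list(vol = vol, Gx = Gx, Gy = Gy, Gz = Gz, mL = mL, K = K, Sc = Sc, Av = Av)
}

# Boundary patch data: per patch the node set, lumped node weights
# (area/3 sums), face list with areas and outward unit normals, and the
# area-weighted mean patch normal.
patchData <- function(mesh) {
  bf <- mesh@boundaryFaces
  pat <- mesh@boundaryPatch
  v <- mesh@vertices
  a <- v[bf[, 1], , drop = FALSE]
  n <- rowCross(v[bf[, 2], , drop = FALSE] - a, v[bf[, 3], , drop = FALSE] - a)
  areas <- 0.5 * rowNorms(n)
  nunit <- normalizeRows(n)
  out <- list()
  for (p in unique(pat)) {
    idx <- which(pat == p)
    nodes <- sort(unique(as.integer(bf[idx, ])))
    w <- as.numeric(Matrix::sparseMatrix(
      i = as.integer(bf[idx, ]), j = rep(1L, 3L * length(idx)),
      x = rep(areas[idx] / 3, 3), dims = c(nrow(v), 1)))
    nbar <- colSums(nunit[idx, , drop = FALSE] * areas[idx])
    # a wrap-around wall patch has no meaningful mean normal
    nbar <- if (vnorm(nbar) > 1e-9 * sum(areas[idx])) unitv(nbar) else c(0, 0, 0)
    out[[p]] <- list(faces = idx, nodes = nodes, nodeW = w,
                     area = sum(areas[idx]), normal = nbar,
                     faceAreas = areas[idx],
                     faceNormals = nunit[idx, , drop = FALSE])
  }
  out
}

# Flux of a nodal vector field through a patch (positive along the stored
# outward face normals): sum over faces of area * mean nodal (u . n).
patchFlux <- function(U, mesh, pd) {
  bf <- mesh@boundaryFaces[pd$faces, , drop = FALSE]
  un <- (U[bf[, 1], , drop = FALSE] + U[bf[, 2], , drop = FALSE] +
           U[bf[, 3], , drop = FALSE]) / 3
  sum(pd$faceAreas * rowSums(un * pd$faceNormals))
}

# Outward vertex normals on the mesh boundary (area-weighted face average).
boundaryVertexNormals <- function(mesh) {
  bf <- mesh@boundaryFaces
  v <- mesh@vertices
  a <- v[bf[, 1], , drop = FALSE]
  n <- rowCross(v[bf[, 2], , drop = FALSE] - a, v[bf[, 3], , drop = FALSE] - a)
  acc <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    s <- Matrix::sparseMatrix(i = as.integer(bf), j = rep(1L, 3L * nrow(bf)),
                              x = rep(n[, k] / 2, 3), dims = c(nrow(v), 1))
    acc[, k] <- as.numeric(s)
  }
  bnodes <- sort(unique(as.integer(bf)))
  acc[bnodes, ] <- normalizeRows(acc[bnodes, , drop = FALSE])
  list(nodes = bnodes, normals = acc)
}

# Linear operators mapping a nodal velocity field to the consistent surface
# integrals int_phi_i (u . n) ds over the given boundary faces (P1 exact:
# the face mass matrix A/12 * (2,1,1)). Returns one sparse matrix per
# velocity component.
boundaryFluxOperator <- function(mesh, faceIdx) {
  bf <- mesh@boundaryFaces[faceIdx, , drop = FALSE]
  v <- mesh@vertices
  a <- v[bf[, 1], , drop = FALSE]
  nvec <- rowCross(v[bf[, 2], , drop = FALSE] - a,
                   v[bf[, 3], , drop = FALSE] - a) / 2 # area-weighted normal
  nv <- nrow(v)
  mk <- function(comp) {
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (r in 1:3) for (cc in 1:3) {
      w <- ifelse(r == cc, 2, 1) / 12
      ii <- c(ii, bf[, r]); jj <- c(jj, bf[, cc])
      xx <- c(xx, w * nvec[, comp])
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv))
  }
  list(SX = mk(1), SY = mk(2), SZ = mk(3))
}
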