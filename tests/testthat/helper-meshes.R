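# Shared fixtures, all built in code.

unitCubeMesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  triSurfaceMesh(v, f)
}

sphereMesh <- function(r = 1, nTheta = 16, nPhi = 24) {
  m <- atriflow:::ellipsoidMesh(c(r, r, r), nTheta, nPhi)
  m
}

randomRotation <- function() {
  A <- matrix(rnorm(9), 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 3] <- -R[, 3]
  R
}

# A small box tet mesh with a named outlet patch for advection tests:
# [0,L]^3 box; the face x = L is the OUT patch, the rest WALL.
boxTetMesh <- function(L = 1, h = 0.25) {
  cube <- unitCubeMesh()
  cube@vertices <- cube@vertices * L
  tm <- tetrahedralize(cube, h)
  ctr <- (tm@vertices[tm@boundaryFaces[, 1], , drop = FALSE] +
            tm@vertices[tm@boundaryFaces[, 2], , drop = FALSE] +
            tm@vertices[tm@boundaryFaces[, 3], , drop = FALSE]) / 3
  tm@boundaryPatch <- ifelse(ctr[, 1] > L - 1e-9, "OUT", "WALL")
  tm
}

# FlowFieldSeries with a prescribed steady nodal velocity on a tet mesh.
steadySeries <- function(tm, U, nT = 3, dt = 0.5) {
  arr <- array(0, c(nrow(tm@vertices), 3, nT))
  for (s in seq_len(nT)) arr[, , s] <- U
  methods::new("FlowFieldSeries", mesh = tm, times = (seq_len(nT) - 1) * dt,
               velocity = arr, pressure = NULL,
               displacementMode = matrix(0, nrow(tm@vertices), 3),
               motionFrequency = 0,
               flowrates = data.frame(time = numeric(0)))
}

# Independent brute-force SDF oracle: plain-R ray casting with its own
# deterministic Fibonacci-spiral cone sampling, written apart from the
# package implementation (vectorized Moeller-Trumbore over faces).
oracleSDF <- function(mesh, coneHalfAngle, nRays) {
  v <- mesh@vertices; f <- mesh@faces
  A <- v[f[, 1], , drop = FALSE]
  E1 <- v[f[, 2], , drop = FALSE] - A
  E2 <- v[f[, 3], , drop = FALSE] - A
  FN <- atriflow:::rowCross(E1, E2)
  ctr <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  nrm <- FN / sqrt(rowSums(FN^2))
  r <- seq_len(nRays)
  theta <- acos(1 - (r - 0.5) / nRays * (1 - cos(coneHalfAngle)))
  phi <- (pi * (3 - sqrt(5))) * r
  w <- 1 / pmax(theta, max(coneHalfAngle, 1e-6) / 30)
  castOne <- function(o, d, excl, n0) {
    P <- cbind(d[2] * E2[, 3] - d[3] * E2[, 2],
               d[3] * E2[, 1] - d[1] * E2[, 3],
               d[1] * E2[, 2] - d[2] * E2[, 1])
    det <- rowSums(E1 * P)
    S <- sweep(-A, 2, o, "+")
    uu <- rowSums(S * P) / det
    Q <- atriflow:::rowCross(S, E1)
    vv <- as.numeric(Q %*% d) / det
    tt <- rowSums(E2 * Q) / det
    ok <- abs(det) > 1e-14 & uu >= -1e-10 & vv >= -1e-10 & uu + vv <= 1 + 1e-10 &
      tt > 1e-6 & seq_len(nrow(f)) != excl & (FN %*% n0) <= 0
    if (!any(ok)) return(NA_real_)
    min(tt[ok])
  }
  vapply(seq_len(nrow(f)), function(i) {
    n <- nrm[i, ]
    e1 <- E1[i, ] - sum(E1[i, ] * n) * n
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- atriflow:::pracma_cross(n, e1)
    lens <- vapply(seq_len(nRays), function(r) {
      d <- -cos(theta[r]) * n +
        sin(theta[r]) * (cos(phi[r]) * e1 + sin(phi[r]) * e2)
      castOne(ctr[i, ], d, i, n)
    }, numeric(1))
    ok <- is.finite(lens)
    lens <- lens[ok]; ww <- w[ok]
    med <- median(lens)
    s <- if (length(lens) > 1) sd(lens) else 0
    keep <- abs(lens - med) <= s + 1e-12
    sum(lens[keep] * ww[keep]) / sum(ww[keep])
  }, numeric(1))
}
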