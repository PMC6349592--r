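# Ostium grafting: rigid (optionally uniformly scaled) ICP alignment of the
# donor appendage rim onto the template ostium, followed by seam stitching
# and local smoothing. Produces composite atrial models that share the
# template chamber bit-for-bit outside the seam band.

#' Construct a rigid (optionally scaled) transform
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (cm).
#' @param scale uniform scale factor.
#' @return a \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  new("RigidTransform", rotation = rotation, translation = translation,
      scale = scale)
}

#' Closed-form least-squares rigid fit (Kabsch/Umeyama)
#'
#' @param src,dst n x 3 matched point sets.
#' @param withScale estimate a uniform scale (Umeyama) or keep scale 1.
#' @return a \linkS4class{RigidTransform} mapping \code{src} onto \code{dst}.
#' @keywords internal
kabschFit <- function(src, dst, withScale = FALSE) {
  cs <- colMeans(src); cd <- colMeans(dst)
  X <- sweep(src, 2, cs); Y <- sweep(dst, 2, cd)
  S <- crossprod(X, Y)
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  Dm <- diag(c(1, 1, d))
  R <- sv$v %*% Dm %*% t(sv$u)
  s <- if (withScale) sum(diag(Dm) * sv$d) / sum(X^2) else 1
  t <- cd - s * as.vector(R %*% cs)
  new("RigidTransform", rotation = R, translation = t, scale = s)
}

#' Iterative closest point registration of two point sets
#'
#' Alternates nearest-neighbor matching of the floating set against the
#' fixed set with a closed-form least-squares rigid (optionally uniformly
#' scaled) fit, after initialization by centroid alignment and
#' principal-axes rotation. Stops when the RMS change falls below \code{tol}
#' or after \code{maxIter} iterations.
#'
#' @param floating n x 3 floating point set (moved onto the fixed set).
#' @param fixed m x 3 fixed point set.
#' @param maxIter maximum ICP iterations.
#' @param tol RMS-change stopping tolerance.
#' @param withScale also estimate a uniform scale factor.
#' @return list with \code{transform} (\linkS4class{RigidTransform}),
#'   \code{rms}, \code{iterations} and the per-iteration \code{rmsHistory}.
#' @export
icpAlign <- function(floating, fixed, maxIter = 100L, tol = 1e-10,
                     withScale = FALSE) {
  floating <- as.matrix(floating); fixed <- as.matrix(fixed)
  if (nrow(floating) < 3 || nrow(fixed) < 3)
    stop("need at least 3 points in each set")
  for (nmset in list(floating, fixed)) {
    sv <- svd(sweep(nmset, 2, colMeans(nmset)))$d
    if (sv[2] < 1e-9 * max(sv[1], 1e-300))
      stop("degenerate (collinear) point set")
  }
  nn <- function(pts) {
    # nearest fixed point for each row of pts
    d2 <- outer(rowSums(pts^2), rowSums(fixed^2), "+") - 2 * pts %*% t(fixed)
    fixed[max.col(-d2, ties.method = "first"), , drop = FALSE]
  }
  # initialization: centroids + principal axes (best of the 4 proper flips)
  cf <- colMeans(floating); cx <- colMeans(fixed)
  Pf <- svd(sweep(floating, 2, cf))$v
  Px <- svd(sweep(fixed, 2, cx))$v
  if (det(Pf) < 0) Pf[, 3] <- -Pf[, 3]
  if (det(Px) < 0) Px[, 3] <- -Px[, 3]
  best <- NULL
  for (flip in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    R0 <- Px %*% diag(flip) %*% t(Pf)
    cand <- sweep(sweep(floating, 2, cf) %*% t(R0), 2, cx, "+")
    r <- sqrt(mean(rowSums((cand - nn(cand))^2)))
    if (is.null(best) || r < best$r)
      best <- list(r = r, R = R0, t = cx - as.vector(R0 %*% cf))
  }
  Tcur <- new("RigidTransform", rotation = best$R, translation = best$t, scale = 1)
  rmsHist <- numeric(0)
  rmsPrev <- Inf
  pts <- applyTransform(floating, Tcur)
  for (it in seq_len(maxIter)) {
    matched <- nn(pts)
    Tstep <- kabschFit(pts, matched, withScale = withScale)
    pts <- applyTransform(pts, Tstep)
    # compose: x -> s2 R2 (s1 R1 x + t1) + t2
    Tcur <- new("RigidTransform",
                rotation = Tstep@rotation %*% Tcur@rotation,
                translation = Tstep@scale * as.vector(Tstep@rotation %*% Tcur@translation) +
                  Tstep@translation,
                scale = Tstep@scale * Tcur@scale)
    rms <- sqrt(mean(rowSums((pts - nn(pts))^2)))
    rmsHist <- c(rmsHist, rms)
    if (abs(rmsPrev - rms) < tol) break
    rmsPrev <- rms
  }
  list(transform = Tcur, rms = rmsHist[length(rmsHist)], iterations = it,
       rmsHistory = rmsHist)
}

# Cyclic correspondence between two rims: resamples both loops to a common
# count and finds the offset/orientation minimizing total correspondence
# length (smallest offset wins ties).
rimCorrespondence <- function(fixedLoop, floatLoop, n = NULL) {
  if (is.null(n)) n <- max(nrow(fixedLoop), nrow(floatLoop), 32)
  resample <- function(loop) {
    closed <- rbind(loop, loop[1, ])
    cs <- cumArclength(closed)
    polylineAt(closed, seq(0, cs[length(cs)], length.out = n + 1)[-(n + 1)])
  }
  A <- resample(fixedLoop)
  ors <- list(fwd = 1:n, rev = n:1)
  best <- NULL
  for (onm in names(ors)) {
    B <- resample(floatLoop[if (onm == "fwd") seq_len(nrow(floatLoop))
                            else rev(seq_len(nrow(floatLoop))), , drop = FALSE])
    for (off in 0:(n - 1)) {
      idx <- ((seq_len(n) - 1 + off) %% n) + 1
      tot <- sum(rowNorms(A - B[idx, , drop = FALSE]))
      if (is.null(best) || tot < best$tot - 1e-12)
        best <- list(tot = tot, offset = off, orientation = onm, A = A,
                     B = B[idx, , drop = FALSE])
    }
  }
  best
}

#' Graft a donor LAA onto the open template atrium
#'
#' Transforms the donor (by the given transform, or an ICP alignment of the
#' two ostium rims), stitches the two rims with a triangle strip chosen to
#' minimize seam length with minimal twist, and relaxes a 2-ring band around
#' the seam by Laplacian smoothing. The composite is closed except for the
#' template's PV/MV ports.
#'
#' @param templateOpen template mesh with an \code{OSTIUM} boundary loop
#'   (and its other ports tagged).
#' @param laa donor appendage mesh with one \code{OSTIUM} boundary loop.
#' @param transform optional \linkS4class{RigidTransform}; computed by
#'   \code{\link{icpAlign}} on the rims when \code{NULL}.
#' @param orientation \code{"auto"} picks the rim orientation with the
#'   least seam twist; \code{"keep"}/\code{"flip"} force one (a forced wrong
#'   orientation raises the self-intersecting-seam error).
#' @param apexDirection optional unit vector: after registration the donor
#'   is spun about the ostium axis so its apex points this way. Near-circular
#'   rims leave the azimuth unconstrained, so comparative studies should pin
#'   it to one anatomical direction for every donor (only applied when the
#'   transform is computed internally).
#' @param smoothIterations seam-band smoothing sweeps.
#' @param details also return the transform and donor vertex range.
#' @return the composite \linkS4class{TriSurfaceMesh}, or (with
#'   \code{details}) a list with \code{composite}, \code{transform} and
#'   \code{donorVertexOffset}.
#' @export
graftLAA <- function(templateOpen, laa, transform = NULL,
                     orientation = c("auto", "keep", "flip"),
                     apexDirection = NULL,
                     smoothIterations = 3L, details = FALSE) {
  orientation <- match.arg(orientation)
  tLoop <- templateOpen@portTags$OSTIUM
  lLoop <- laa@portTags$OSTIUM
  if (is.null(tLoop) || is.null(lLoop))
    stop("both meshes must carry an OSTIUM port tag")
  tRim <- templateOpen@vertices[tLoop, , drop = FALSE]
  if (is.null(transform)) {
    transform <- icpAlign(laa@vertices[lLoop, , drop = FALSE], tRim)$transform
    # rim-only registration cannot see sidedness: the appendage must point
    # away from the chamber. If the apex lands inside, rotate the donor by
    # pi about an in-plane rim axis and re-refine.
    ctrR <- colMeans(tRim)
    outward <- unitv(ctrR - colMeans(templateOpen@vertices))
    lrc <- colMeans(laa@vertices[lLoop, , drop = FALSE])
    apexL <- laa@vertices[which.max(rowNorms(sweep(laa@vertices, 2, lrc))), ]
    apexT <- as.vector(applyTransform(matrix(apexL, 1, 3), transform))
    if (sum((apexT - ctrR) * outward) < 0) {
      a <- unitv(tRim[1, ] - ctrR)
      Rf <- 2 * (a %o% a) - diag(3)
      transform <- new("RigidTransform",
                       rotation = Rf %*% transform@rotation,
                       translation = as.vector(ctrR - Rf %*% ctrR) +
                         as.vector(Rf %*% transform@translation),
                       scale = transform@scale)
      pts <- applyTransform(laa@vertices[lLoop, , drop = FALSE], transform)
      for (it in 1:25) {
        d2 <- outer(rowSums(pts^2), rowSums(tRim^2), "+") - 2 * pts %*% t(tRim)
        matched <- tRim[max.col(-d2, ties.method = "first"), , drop = FALSE]
        Tstep <- kabschFit(pts, matched)
        pts <- applyTransform(pts, Tstep)
        transform <- new("RigidTransform",
                         rotation = Tstep@rotation %*% transform@rotation,
                         translation = as.vector(Tstep@rotation %*% transform@translation) +
                           Tstep@translation,
                         scale = transform@scale)
      }
    }
    if (!is.null(apexDirection)) {
      # spin about the ostium axis so the apex points the prescribed way
      ctrR <- colMeans(tRim)
      ax <- svd(sweep(tRim, 2, ctrR))$v[, 3]
      if (sum(ax * (ctrR - colMeans(templateOpen@vertices))) < 0) ax <- -ax
      lrc <- colMeans(laa@vertices[lLoop, , drop = FALSE])
      apexL <- laa@vertices[which.max(rowNorms(sweep(laa@vertices, 2, lrc))), ]
      apexT <- as.vector(applyTransform(matrix(apexL, 1, 3), transform))
      perp <- function(v) v - sum(v * ax) * ax
      a1 <- perp(apexT - ctrR); a2 <- perp(unitv(apexDirection))
      if (vnorm(a1) > 1e-9 && vnorm(a2) > 1e-9) {
        a1 <- unitv(a1); a2 <- unitv(a2)
        ang <- atan2(sum(pracma_cross(a1, a2) * ax), sum(a1 * a2))
        K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
                   c(-ax[2], ax[1], 0))
        Rspin <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
        transform <- new("RigidTransform",
                         rotation = Rspin %*% transform@rotation,
                         translation = as.vector(ctrR - Rspin %*% ctrR) +
                           as.vector(Rspin %*% transform@translation),
                         scale = transform@scale)
      }
    }
  }
  laaT <- applyTransform(laa, transform)
  lRim <- laaT@vertices[lLoop, , drop = FALSE]
  perRatio <- arclength(rbind(tRim, tRim[1, ])) / arclength(rbind(lRim, lRim[1, ]))
  if (perRatio > 3 || perRatio < 1 / 3)
    warning(sprintf("ostium perimeter ratio %.2f exceeds 3x; proceeding", perRatio))

  # seam twist per orientation: spokes should wind monotonically about the
  # common rim axis, so the median angular mismatch discriminates a flipped rim
  ctr <- (colMeans(tRim) + colMeans(lRim)) / 2
  pl <- svd(sweep(rbind(tRim, lRim), 2, ctr))$v
  axis <- pl[, 3] # rim-plane normal
  e1 <- orthoVector(axis); e2 <- pracma_cross(axis, e1)
  ang <- function(p) atan2(sweep(p, 2, ctr) %*% e2, sweep(p, 2, ctr) %*% e1)
  twist <- function(corr) {
    da <- as.vector(ang(corr$A)) - as.vector(ang(corr$B))
    da <- atan2(sin(da), cos(da))
    median(abs(da))
  }
  # forced orientations: restrict the correspondence search
  corrOriented <- function(dirn) {
    n <- max(nrow(tRim), nrow(lRim), 32)
    resample <- function(loop) {
      closed <- rbind(loop, loop[1, ])
      cs <- cumArclength(closed)
      polylineAt(closed, seq(0, cs[length(cs)], length.out = n + 1)[-(n + 1)])
    }
    A <- resample(tRim)
    B <- resample(if (dirn == "keep") lRim else lRim[rev(seq_len(nrow(lRim))), , drop = FALSE])
    best <- NULL
    for (off in 0:(n - 1)) {
      idx <- ((seq_len(n) - 1 + off) %% n) + 1
      tot <- sum(rowNorms(A - B[idx, , drop = FALSE]))
      if (is.null(best) || tot < best$tot - 1e-12)
        best <- list(tot = tot, A = A, B = B[idx, , drop = FALSE], dirn = dirn)
    }
    best
  }
  corr <- switch(orientation,
                 auto = {
                   ck <- corrOriented("keep"); cf <- corrOriented("flip")
                   if (twist(ck) <= twist(cf)) ck else cf
                 },
                 keep = corrOriented("keep"),
                 flip = corrOriented("flip"))
  if (twist(corr) > pi / 3)
    stop("self-intersecting seam: rim correspondence twists by ",
         sprintf("%.0f", twist(corr) * 180 / pi), " degrees")

  # assemble composite: template + transformed donor + seam strip through
  # the resampled intermediate ring (midway between the two rims)
  nT <- nrow(templateOpen@vertices)
  v <- rbind(templateOpen@vertices, laaT@vertices)
  f <- rbind(templateOpen@faces, laaT@faces + nT)
  comp <- triSurfaceMesh(v, f)
  zipT <- zipperStrip(comp, tLoop, lLoop + nT)
  f <- rbind(f, zipT)
  tags <- templateOpen@portTags
  tags$OSTIUM <- NULL
  out <- triSurfaceMesh(v, f, portTags = tags)
  # seam band: the two rims and their 2-ring neighborhoods
  if (smoothIterations > 0) {
    seamV <- unique(c(tLoop, lLoop + nT))
    adj <- vertexAdjacency(out)
    band <- seamV
    for (r in 1:2) band <- unique(c(band, unlist(adj[band])))
    fixedV <- setdiff(seq_len(nrow(v)), band)
    out <- laplacianSmooth(out, iterations = smoothIterations,
                           relaxation = 0.4, fixed = fixedV)
  }
  if (details)
    list(composite = out, transform = transform, donorVertexOffset = nT)
  else out
}

# Greedy zipper triangulation between two boundary loops of one mesh.
# Loops are given as vertex index vectors; their directed-boundary senses
# are opposite (they bound the surface on opposite sides), so the zipper
# walks one forward and the other backward from the closest starting pair.
zipperStrip <- function(mesh, loopA, loopB) {
  v <- mesh@vertices
  # directed boundary order as walked by boundaryLoops
  loops <- boundaryLoops(mesh)
  findLoop <- function(lv) {
    for (l in loops)
      if (length(l) == length(lv) && all(sort(l) == sort(lv))) return(l)
    stop("loop not found on composite boundary")
  }
  A <- findLoop(loopA)
  B <- rev(findLoop(loopB))
  na <- length(A); nb <- length(B)
  pa <- v[A, , drop = FALSE]; pb <- v[B, , drop = FALSE]
  # start at the closest pair
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  st <- arrayInd(which.min(d2), dim(d2))
  ia <- st[1]; ib <- st[2]
  f <- matrix(0L, na + nb, 3)
  k <- 0
  ca <- 0; cb <- 0
  while (ca < na || cb < nb) {
    ja <- A[(ia %% na) + 1]; jb <- B[(ib %% nb) + 1]
    advA <- if (ca >= na) FALSE
            else if (cb >= nb) TRUE
            else sum((v[ja, ] - v[B[ib], ])^2) <= sum((v[jb, ] - v[A[ia], ])^2)
    k <- k + 1
    if (advA) {
      # triangle (A_next, A_cur, B_cur): A walked against its boundary sense
      f[k, ] <- c(ja, A[ia], B[ib])
      ia <- (ia %% na) + 1; ca <- ca + 1
    } else {
      f[k, ] <- c(B[ib], jb, A[ia])
      ib <- (ib %% nb) + 1; cb <- cb + 1
    }
  }
  f[seq_len(k), , drop = FALSE]
}

#' Build the composite model set from one template and several donors
#'
#' Grafts each donor appendage onto the same open template; all composites
#' share the template chamber coordinates outside the seam band.
#'
#' @param template template mesh with tagged \code{OSTIUM}.
#' @param donorLAAs list of donor meshes (each with an \code{OSTIUM} tag).
#' @param details return transforms alongside the composites.
#' @param ... passed to \code{\link{graftLAA}}.
#' @return named list of composite meshes (\code{LAA1}, \code{LAA2}, ...),
#'   or of detail lists when \code{details = TRUE}.
#' @export
buildModelSet <- function(template, donorLAAs, details = FALSE, ...) {
  if (length(donorLAAs) == 0) return(list())
  out <- lapply(donorLAAs, function(d)
    graftLAA(template, d, details = details, ...))
  names(out) <- paste0("LAA", seq_along(out))
  out
}
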