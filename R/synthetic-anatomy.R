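# Parametric left-atrium and LAA generator. Synthetic anatomies carry
# analytically known ground truth (centerline length, endpoint distance,
# tortuosity, approximate volume and lateral area) and emulate the geometric
# ranges reported for patient appendages: volume ~2.0-2.6 cm^3, length
# ~2.3-3.5 cm, tortuosity ~0.03-0.46. All dimensions in cm.

#' Specification of a swept-tube LAA
#'
#' The appendage is a circular tube swept along a cubic spline through the
#' control points using rotation-minimizing frames, closed distally by a
#' spherical cap and open proximally (the ostium rim).
#'
#' @param controlPoints n x 3 matrix (n >= 2) of spline control points (cm).
#' @param radius base tube radius (cm), or a function of normalized
#'   arclength s in [0,1] returning the radius.
#' @param taper linear taper fraction: with scalar \code{radius} r0 the
#'   profile is \code{r0 * (1 - taper * s)}; mimics appendages that shrink
#'   toward the distal part.
#' @param samples number of sweep stations along the spline.
#' @param nRing vertices per cross-section ring.
#' @param seed integer seed (kept for reproducibility metadata).
#' @return a validated list of class \code{laaCurveSpec}.
#' @export
laaCurveSpec <- function(controlPoints, radius = 0.5, taper = 0,
                         samples = 50, nRing = 20, seed = 1L) {
  controlPoints <- as.matrix(controlPoints)
  if (nrow(controlPoints) < 2) stop("need at least 2 control points")
  if (is.function(radius)) {
    prof <- radius
  } else {
    if (radius <= 0) stop("radius must be positive")
    if (taper < 0 || taper >= 1) stop("taper must be in [0, 1)")
    r0 <- radius
    prof <- function(s) r0 * (1 - taper * s)
  }
  if (any(prof(seq(0, 1, length.out = 64)) <= 0))
    stop("radius profile must be strictly positive")
  structure(list(controlPoints = controlPoints, profile = prof,
                 samples = as.integer(samples), nRing = as.integer(nRing),
                 seed = as.integer(seed)),
            class = "laaCurveSpec")
}

# Sample the spec's spline densely; returns points, cumulative arclength.
sampleSpline <- function(controlPoints, n) {
  if (nrow(controlPoints) == 2) {
    tseq <- seq(0, 1, length.out = n)
    pts <- outer(1 - tseq, controlPoints[1, ]) + outer(tseq, controlPoints[2, ])
    return(pts)
  }
  chord <- c(0, cumsum(rowNorms(diff(controlPoints))))
  u <- chord / chord[length(chord)]
  tseq <- seq(0, 1, length.out = n)
  sapply(1:3, function(k)
    splinefun(u, controlPoints[, k], method = "natural")(tseq))
}

# Double-reflection rotation-minimizing frames along a polyline.
rmfFrames <- function(pts) {
  n <- nrow(pts)
  tg <- matrix(0, n, 3)
  tg[1, ] <- unitv(pts[2, ] - pts[1, ])
  tg[n, ] <- unitv(pts[n, ] - pts[n - 1, ])
  if (n > 2)
    for (i in 2:(n - 1)) tg[i, ] <- unitv(pts[i + 1, ] - pts[i - 1, ])
  e1 <- matrix(0, n, 3)
  e1[1, ] <- orthoVector(tg[1, ])
  for (i in seq_len(n - 1)) {
    v1 <- pts[i + 1, ] - pts[i, ]
    c1 <- sum(v1 * v1)
    rL <- e1[i, ] - (2 / c1) * sum(v1 * e1[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    e1[i + 1, ] <- if (c2 < 1e-300) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    e1[i + 1, ] <- unitv(e1[i + 1, ] - sum(e1[i + 1, ] * tg[i + 1, ]) * tg[i + 1, ])
  }
  e2 <- rowCross(tg, e1)
  list(t = tg, e1 = e1, e2 = e2)
}

# Reject swept tubes that would self-intersect: non-adjacent stations must
# be separated by more than the sum of local radii, and the tube radius must
# stay below the local radius of curvature.
checkTubeEmbedding <- function(pts, radii) {
  n <- nrow(pts)
  s <- cumArclength(pts)
  d2 <- as.matrix(dist(pts))
  sepArc <- abs(outer(s, s, "-"))
  rsum <- outer(radii, radii, "+")
  viol <- d2 < 0.99 * rsum & sepArc > 1.5 * rsum
  if (any(viol)) {
    ij <- which(viol, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "tube self-intersects: stations at arclength %.2f and %.2f cm come within %.3f cm (radii sum %.3f cm)",
      s[ij[1]], s[ij[2]], d2[ij[1], ij[2]], rsum[ij[1], ij[2]]))
  }
  if (n > 2) {
    # discrete curvature
    for (i in 2:(n - 1)) {
      a <- pts[i, ] - pts[i - 1, ]; b <- pts[i + 1, ] - pts[i, ]
      sinang <- vnorm(pracma_cross(a, b)) / (vnorm(a) * vnorm(b))
      kap <- 2 * sinang / vnorm(pts[i + 1, ] - pts[i - 1, ])
      if (kap * radii[i] > 0.95)
        stop(sprintf(
          "tube self-intersects: curvature radius %.3f cm below tube radius %.3f cm at arclength %.2f cm",
          1 / max(kap, 1e-12), radii[i], s[i]))
    }
  }
  invisible(TRUE)
}

#' Generate a parametric LAA tube with known ground truth
#'
#' Sweeps a circle of the spec's radius profile along the spline with
#' rotation-minimizing frames (no twist), caps the distal end with a
#' spherical cap, and leaves the proximal ring open as the ostium rim
#' (tagged \code{OSTIUM}).
#'
#' Ground truth refers to the swept spline: \code{L} is its arclength,
#' \code{D} the endpoint distance, \code{chi = L/D - 1} the tortuosity,
#' \code{V} and \code{As} quadrature estimates of the enclosed volume and
#' lateral surface area (tube + distal cap).
#'
#' @param spec an \code{\link{laaCurveSpec}}.
#' @return list with elements \code{mesh} (\linkS4class{TriSurfaceMesh})
#'   and \code{truth} (list L, D, chi, V, As).
#' @export
makeParametricLAA <- function(spec) {
  stopifnot(inherits(spec, "laaCurveSpec"))
  nf <- 1200
  fine <- sampleSpline(spec$controlPoints, nf)
  sFine <- cumArclength(fine)
  L <- sFine[nf]
  if (L <= 0) stop("degenerate spline: zero length")
  D <- vnorm(fine[nf, ] - fine[1, ])
  if (D <= 0) stop("closed-loop splines are not supported")
  rFine <- spec$profile(sFine / L)
  rtip <- rFine[nf]
  # quadrature ground truth (trapezoid) + spherical cap
  ds <- diff(sFine)
  V <- sum(ds * (rFine[-1]^2 + rFine[-nf]^2) / 2) * pi + 2 / 3 * pi * rtip^3
  As <- sum(ds * (rFine[-1] + rFine[-nf])) * pi + 2 * pi * rtip^2
  truth <- list(L = L, D = D, chi = L / D - 1, V = V, As = As)

  checkTubeEmbedding(fine[seq(1, nf, by = 6), , drop = FALSE],
                     rFine[seq(1, nf, by = 6)])

  ns <- spec$samples
  ctr <- polylineAt(fine, seq(0, L, length.out = ns))
  sCtr <- cumArclength(ctr)
  rCtr <- spec$profile(sCtr / L)
  fr <- rmfFrames(ctr)
  m <- spec$nRing
  alpha <- 2 * pi * (seq_len(m) - 1) / m
  ringAt <- function(center, r, e1, e2)
    sweep(outer(cos(alpha), e1) + outer(sin(alpha), e2), 1, r, "*") +
      matrix(center, m, 3, byrow = TRUE)
  verts <- NULL
  for (i in seq_len(ns))
    verts <- rbind(verts, ringAt(ctr[i, ], rCtr[i], fr$e1[i, ], fr$e2[i, ]))
  # distal spherical cap rings
  nCap <- max(3, ceiling(m / 4))
  capC <- ctr[ns, ]; tEnd <- fr$t[ns, ]
  for (k in seq_len(nCap - 1)) {
    phi <- (pi / 2) * k / nCap
    verts <- rbind(verts, ringAt(capC + rtip * sin(phi) * tEnd,
                                 rtip * cos(phi), fr$e1[ns, ], fr$e2[ns, ]))
  }
  pole <- capC + rtip * tEnd
  verts <- rbind(verts, pole)
  poleIdx <- nrow(verts)

  stripFaces <- function(r0, r1) {
    # quads between ring starting at vertex index r0 and ring at r1
    j <- seq_len(m); jn <- c(2:m, 1)
    rbind(cbind(r0 + j, r0 + jn, r1 + jn),
          cbind(r0 + j, r1 + jn, r1 + j))
  }
  f <- NULL
  nRings <- ns + nCap - 1
  for (i in seq_len(nRings - 1))
    f <- rbind(f, stripFaces((i - 1) * m, i * m))
  lastR <- (nRings - 1) * m
  j <- seq_len(m); jn <- c(2:m, 1)
  f <- rbind(f, cbind(lastR + j, lastR + jn, rep(poleIdx, m)))
  mesh <- triSurfaceMesh(verts, f, portTags = list(OSTIUM = seq_len(m)))
  list(mesh = mesh, truth = truth)
}

#' Specification of the template left atrium
#'
#' An ellipsoidal chamber with four pulmonary vein (PV) tubes, a mitral
#' valve (MV) port and an LAA ostium port, each defined by a radial
#' direction from the chamber center, a port radius and a loft length.
#' Defaults give a physiologic chamber volume of roughly 100 ml; the port
#' layout mimics the usual PV/MV/LAA arrangement.
#'
#' @param semiAxes ellipsoid semi-axes (cm).
#' @param pvPorts list of 4 lists with \code{direction}, \code{radius},
#'   \code{length}.
#' @param mvPort,ostiumPort single port specs of the same shape;
#'   \code{ostiumPort = NULL} builds an atrium without an appendage port.
#' @param nTheta,nPhi ellipsoid mesh resolution.
#' @return a validated list of class \code{templateLASpec}.
#' @export
templateLASpec <- function(
    semiAxes = c(3.5, 2.8, 2.4),
    pvPorts = list(
      list(direction = c(0.5, 0.7, 0.5), radius = 0.8, length = 1.3),
      list(direction = c(0.8, 0.55, -0.35), radius = 0.8, length = 1.3),
      list(direction = c(-0.5, 0.7, 0.5), radius = 0.8, length = 1.3),
      list(direction = c(-0.8, 0.55, -0.35), radius = 0.8, length = 1.3)),
    mvPort = list(direction = c(0.15, -0.2, -1), radius = 1.2, length = 0.6),
    ostiumPort = list(direction = c(-0.55, -0.1, -0.5), radius = 0.72,
                      length = 0.3),
    nTheta = 40, nPhi = 64) {
  ports <- c(stats::setNames(pvPorts, paste0("PV", 1:4)), list(MV = mvPort))
  if (!is.null(ostiumPort)) ports$OSTIUM <- ostiumPort
  for (nm in names(ports)) {
    p <- ports[[nm]]
    if (p$radius <= 0) stop("port ", nm, " has non-positive radius")
    if (p$length <= 0) stop("port ", nm, " has non-positive length")
    ports[[nm]]$direction <- unitv(p$direction)
  }
  # surface anchor points; reject overlapping ports
  anchor <- function(d) d / sqrt(sum((d / semiAxes)^2))
  qs <- t(vapply(ports, function(p) anchor(p$direction), numeric(3)))
  for (i in seq_len(nrow(qs) - 1)) for (j in (i + 1):nrow(qs)) {
    need <- 1.25 * (ports[[i]]$radius + ports[[j]]$radius)
    if (vnorm(qs[i, ] - qs[j, ]) < need)
      stop("ports ", names(ports)[i], " and ", names(ports)[j],
           " overlap on the chamber surface")
  }
  structure(list(semiAxes = semiAxes, ports = ports,
                 nTheta = as.integer(nTheta), nPhi = as.integer(nPhi)),
            class = "templateLASpec")
}

# UV-sphere ellipsoid mesh.
ellipsoidMesh <- function(semiAxes, nTheta, nPhi) {
  th <- pi * seq_len(nTheta - 1) / nTheta
  ph <- 2 * pi * (seq_len(nPhi) - 1) / nPhi
  grid <- expand.grid(ph = ph, th = th)
  v <- cbind(sin(grid$th) * cos(grid$ph), sin(grid$th) * sin(grid$ph),
             cos(grid$th))
  v <- rbind(c(0, 0, 1), v, c(0, 0, -1))
  v <- sweep(v, 2, semiAxes, "*")
  idx <- function(i, j) 1 + (i - 1) * nPhi + ((j - 1) %% nPhi) + 1
  f <- NULL
  # top fan (north pole = vertex 1); outward orientation (CCW from outside)
  j <- seq_len(nPhi)
  f <- rbind(f, cbind(1, idx(1, j), idx(1, j + 1)))
  if (nTheta > 2) for (i in seq_len(nTheta - 2)) {
    f <- rbind(f,
               cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  south <- nrow(v)
  f <- rbind(f, cbind(south, idx(nTheta - 1, j + 1), idx(nTheta - 1, j)))
  triSurfaceMesh(v, f)
}

#' Build the template left atrium
#'
#' Meshes the ellipsoidal chamber, opens a hole at each port anchor and
#' lofts it to a circular rim of the port radius at the port length,
#' producing an open tube per port. The six open boundary loops are tagged
#' \code{PV1}..\code{PV4}, \code{MV} and \code{OSTIUM}.
#'
#' @param spec a \code{\link{templateLASpec}}.
#' @return a \linkS4class{TriSurfaceMesh} with exactly six boundary loops.
#' @export
makeTemplateLA <- function(spec = templateLASpec()) {
  stopifnot(inherits(spec, "templateLASpec"))
  mesh <- ellipsoidMesh(spec$semiAxes, spec$nTheta, spec$nPhi)
  anchor <- function(d) d / sqrt(sum((d / spec$semiAxes)^2))
  tags <- list()
  for (nm in names(spec$ports)) {
    p <- spec$ports[[nm]]
    q <- anchor(p$direction)
    cen <- faceCentroids(mesh)
    drop <- which(rowNorms(sweep(cen, 2, q)) < p$radius)
    if (length(drop) < 3)
      stop("port ", nm, " is too small for the mesh resolution")
    keep <- setdiff(seq_len(nrow(mesh@faces)), drop)
    sub <- subsetFaces(mesh, keep)
    holey <- sub$mesh
    # previously tagged port rims survive hole cutting but get renumbered
    tags <- lapply(tags, function(tg) match(tg, sub$vmap))
    loops <- boundaryLoops(holey)
    # the port hole is the newest loop: the one whose vertices lie near q
    distq <- vapply(loops, function(l)
      min(rowNorms(sweep(holey@vertices[l, , drop = FALSE], 2, q))),
      numeric(1))
    li <- which.min(distq)
    loop <- loops[[li]]
    rim <- holey@vertices[loop, , drop = FALSE]
    if (max(rowNorms(sweep(rim, 2, q))) > 3 * p$radius)
      stop("port ", nm, ": hole rim is not simple at this resolution")
    d <- p$direction
    e1 <- orthoVector(d); e2 <- pracma_cross(d, e1)
    relr <- sweep(rim, 2, q)
    alpha <- atan2(relr %*% e2, relr %*% e1)
    target <- matrix(q + p$length * d, length(loop), 3, byrow = TRUE) +
      p$radius * (outer(as.vector(cos(alpha)), e1) +
                  outer(as.vector(sin(alpha)), e2))
    nLoft <- 4
    v <- holey@vertices
    prev <- loop
    nl <- length(loop)
    fnew <- NULL
    for (k in seq_len(nLoft)) {
      tk <- k / nLoft
      ring <- (1 - tk) * (rim + tk * matrix(p$length * d, nl, 3, byrow = TRUE)) +
        tk * target
      v <- rbind(v, ring)
      cur <- (nrow(v) - nl + 1):nrow(v)
      jn <- c(2:nl, 1)
      fnew <- rbind(fnew,
                    cbind(prev[jn], prev, cur),
                    cbind(prev[jn], cur, cur[jn]))
      prev <- cur
    }
    mesh <- triSurfaceMesh(v, rbind(holey@faces, fnew),
                           portTags = c(tags, stats::setNames(list(prev), nm)))
    tags <- mesh@portTags
  }
  loops <- boundaryLoops(mesh)
  if (length(loops) != length(spec$ports))
    stop("template construction failed: expected ", length(spec$ports),
         " boundary loops, found ", length(loops))
  mesh
}

#' Generate a synthetic study set of one template and graded LAA variants
#'
#' Produces \code{nVariants} donor appendages with monotonically increasing
#' tortuosity spanning at least [0.03, 0.46] and centerline lengths spanning
#' at least [2.3, 3.5] cm (circular-arc base curves with a seeded
#' out-of-plane perturbation), alongside the default template atrium.
#' Volumes span roughly 2.0-2.6 cm^3 via the tube radius.
#'
#' @param nVariants number of donors (>= 2).
#' @param seed RNG seed; the same seed reproduces identical meshes.
#' @param templateSpec template specification.
#' @return list with \code{template} (mesh), \code{templateSpec} and
#'   \code{donors}: a list of \code{list(mesh, truth, spec)} sorted by
#'   increasing tortuosity.
#' @export
makeStudySet <- function(nVariants, seed = 1L,
                         templateSpec = templateLASpec()) {
  stopifnot(nVariants >= 2)
  template <- makeTemplateLA(templateSpec)
  chiT <- seq(0.02, 0.48, length.out = nVariants)
  lenT <- seq(2.28, 3.55, length.out = nVariants)
  # volume pairs inversely with tortuosity, as in the patient set (the most
  # tortuous appendage is the narrow small-volume one, the straightest has
  # the widest orifice)
  volT <- seq(2.60, 2.05, length.out = nVariants)
  taper <- 0.35
  volFac <- 1 - taper + taper^2 / 3
  donors <- withSeed(seed, lapply(seq_len(nVariants), function(i) {
    theta <- uniroot(function(th) th / (2 * sin(th / 2)) - 1 - chiT[i],
                     c(1e-4, 3.1), tol = 1e-12)$root
    R <- lenT[i] / theta
    phi <- seq(0, theta, length.out = 6)
    arc <- cbind(R * sin(phi), R * (1 - cos(phi)), 0)
    # seeded out-of-plane ripple, small enough to keep the target ranges
    arc[, 3] <- arc[, 3] + 0.02 * lenT[i] * sin(2 * pi * phi / theta) * runif(1)
    tilt <- runif(1, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0),
                c(0, cos(tilt), -sin(tilt)),
                c(0, sin(tilt), cos(tilt)))
    arc <- arc %*% t(Rx)
    r0 <- sqrt(volT[i] / (pi * lenT[i] * volFac))
    # sweep resolution chosen to keep the donor face density comparable to
    # the template's, so the chamber stays the modal region after clustering
    spec <- laaCurveSpec(arc, radius = r0, taper = taper,
                         samples = 32, nRing = 14, seed = seed + i)
    c(makeParametricLAA(spec), list(spec = spec))
  }))
  list(template = template, templateSpec = templateSpec, donors = donors)
}

#' Generate an open cylindrical tube mesh
#'
#' A straight circular tube along +z with open ends tagged \code{INLET}
#' (z = 0) and \code{OUTLET} (z = length); used for solver verification and
#' as an analytic SDF oracle target.
#'
#' @param radius tube radius (cm).
#' @param length tube length (cm).
#' @param nRing vertices per ring.
#' @param nAxial number of rings.
#' @return a \linkS4class{TriSurfaceMesh} with two boundary loops.
#' @export
makeCylinderTube <- function(radius = 0.3, length = 2, nRing = 24,
                             nAxial = 17) {
  al <- 2 * pi * (seq_len(nRing) - 1) / nRing
  z <- seq(0, length, length.out = nAxial)
  v <- do.call(rbind, lapply(z, function(zz)
    cbind(radius * cos(al), radius * sin(al), zz)))
  j <- seq_len(nRing); jn <- c(2:nRing, 1)
  f <- NULL
  for (i in seq_len(nAxial - 1)) {
    r0 <- (i - 1) * nRing; r1 <- i * nRing
    f <- rbind(f, cbind(r0 + j, r0 + jn, r1 + jn), cbind(r0 + j, r1 + jn, r1 + j))
  }
  triSurfaceMesh(v, f, portTags = list(
    INLET = seq_len(nRing), OUTLET = (nAxial - 1) * nRing + seq_len(nRing)))
}
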