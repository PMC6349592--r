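# Stasis post-processing: Q-criterion vortex structures, ostium velocity
# traces and Lagrangian particle residence quantification.

#' Q-criterion of a velocity snapshot
#'
#' Per-cell Q from the P1 (cell-constant) velocity gradient g. Under the
#' printed convention \code{S_ij = g_ij + g_ji}, \code{W_ij = g_ij - g_ji}
#' and \code{Q = (W_ij W_ij - S_ij S_ij) / 2}, which reduces to
#' \code{-2 sum_ij g_ij g_ji}; the standard convention (1/2 inside S and W)
#' gives exactly a quarter of that, with an identical sign pattern, so the
#' Q > 0 vortex regions agree between conventions.
#'
#' @param series a \linkS4class{FlowFieldSeries}, or a \linkS4class{TetMesh}
#'   when passing a raw velocity matrix.
#' @param step snapshot index (default: last), ignored with a raw matrix.
#' @param U optional nV x 3 velocity matrix overriding the series snapshot.
#' @param convention \code{"printed"} or \code{"standard"}.
#' @return a \linkS4class{QCriterionField} (1/s^2 per cell).
#' @export
qCriterion <- function(series, step = NULL, U = NULL,
                       convention = c("printed", "standard")) {
  convention <- match.arg(convention)
  if (is(series, "FlowFieldSeries")) {
    mesh <- series@mesh
    if (is.null(step)) step <- dim(series@velocity)[3]
    if (is.null(U)) U <- series@velocity[, , step]
    tme <- series@times[step]
  } else {
    mesh <- series
    if (is.null(U)) stop("pass U with a raw TetMesh")
    tme <- NA_real_
  }
  ops <- femOperators(mesh)
  g <- lapply(list(ops$Gx, ops$Gy, ops$Gz), function(G)
    as.matrix(G %*% U)) # g[[j]][, i] = d u_i / d x_j
  Q <- -2 * (g[[1]][, 1] * g[[1]][, 1] + g[[2]][, 2] * g[[2]][, 2] +
               g[[3]][, 3] * g[[3]][, 3] +
               2 * g[[2]][, 1] * g[[1]][, 2] +
               2 * g[[3]][, 1] * g[[1]][, 3] +
               2 * g[[3]][, 2] * g[[2]][, 3])
  if (convention == "standard") Q <- Q / 4
  new("QCriterionField", values = Q, convention = convention, time = tme)
}

#' Connected vortex regions (Q > 0)
#'
#' Face-adjacency connected components of the cells with positive Q, sorted
#' by decreasing region volume, each annotated with its mean velocity
#' magnitude when a velocity snapshot is supplied.
#'
#' @param q a \linkS4class{QCriterionField}.
#' @param mesh the \linkS4class{TetMesh}.
#' @param U optional nodal velocity matrix for the speed annotation.
#' @return list of regions: \code{cells}, \code{volume}, \code{meanSpeed}.
#' @export
vortexRegions <- function(q, mesh, U = NULL) {
  pos <- which(q@values > 0)
  if (length(pos) == 0) return(list())
  tt <- mesh@tets
  vol <- tetVolumes(mesh@vertices, tt)
  # shared-face adjacency among positive cells
  sub <- tt[pos, , drop = FALSE]
  fl <- rbind(sub[, c(2, 3, 4)], sub[, c(1, 3, 4)], sub[, c(1, 2, 4)],
              sub[, c(1, 2, 3)])
  fl <- t(apply(fl, 1, sort))
  key <- paste(fl[, 1], fl[, 2], fl[, 3])
  cid <- rep(seq_along(pos), 4)
  o <- order(key)
  key <- key[o]; cid <- cid[o]
  sameK <- key[-1] == key[-length(key)]
  el <- cbind(cid[c(sameK, FALSE)], cid[c(FALSE, sameK)])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < length(pos))
    g <- igraph::add_vertices(g, length(pos) - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  speeds <- if (!is.null(U)) {
    uc <- (U[sub[, 1], , drop = FALSE] + U[sub[, 2], , drop = FALSE] +
             U[sub[, 3], , drop = FALSE] + U[sub[, 4], , drop = FALSE]) / 4
    rowNorms(uc)
  } else rep(NA_real_, length(pos))
  regs <- lapply(split(seq_along(pos), comp), function(idx) {
    list(cells = pos[idx], volume = sum(vol[pos[idx]]),
         meanSpeed = mean(speeds[idx]))
  })
  regs[order(vapply(regs, `[[`, numeric(1), "volume"), decreasing = TRUE)]
}

#' Area-averaged ostium normal velocity trace
#'
#' Samples the velocity series on a triangulated disc spanning the ostium
#' rim (fan about the rim barycenter) and averages the normal component,
#' oriented from the appendage into the chamber: positive values mean LAA
#' emptying, negative filling. Flags a peak emptying velocity below the
#' 20 cm/s washout threshold.
#'
#' @param series a \linkS4class{FlowFieldSeries}.
#' @param rim ordered ostium rim loop coordinates (n x 3).
#' @param laaPoint any point inside the appendage (fixes the orientation).
#' @return an \linkS4class{OstiumTrace}.
#' @export
ostiumVelocity <- function(series, rim, laaPoint) {
  rim <- as.matrix(rim)
  ctr <- colMeans(rim)
  X <- sweep(rim, 2, ctr)
  nrm <- svd(X)$v[, 3]
  if (sum(nrm * (laaPoint - ctr)) > 0) nrm <- -nrm # point into the chamber
  n <- nrow(rim)
  nxt <- c(2:n, 1)
  cen <- (matrix(ctr, n, 3, byrow = TRUE) + rim + rim[nxt, , drop = FALSE]) / 3
  ar <- 0.5 * rowNorms(rowCross(rim - matrix(ctr, n, 3, byrow = TRUE),
                                rim[nxt, , drop = FALSE] - matrix(ctr, n, 3, byrow = TRUE)))
  loc <- cpp_build_locator(series@mesh@vertices, series@mesh@tets)
  # the section rim hugs the wall: pull samples that miss the discrete mesh
  # toward the section center until they land in a cell
  located <- cpp_locate_points(loc, cen, 1e-9)$cell > 0
  for (tshift in c(0.1, 0.2, 0.3, 0.45)) {
    if (all(located)) break
    miss <- which(!located)
    cand <- sweep(cen[miss, , drop = FALSE] * (1 - tshift), 2,
                  tshift * ctr, "+")
    ok <- cpp_locate_points(loc, cand, 1e-9)$cell > 0
    cen[miss[ok], ] <- cand[ok, , drop = FALSE]
    located[miss[ok]] <- TRUE
  }
  if (!any(located)) stop("ostium section lies outside the flow mesh")
  cen <- cen[located, , drop = FALSE]
  ar <- ar[located]
  nT <- dim(series@velocity)[3]
  tr <- numeric(nT)
  fb <- matrix(0, nrow(cen), 3)
  for (s in seq_len(nT)) {
    us <- cpp_interp_field(loc, series@velocity[, , s], cen, fb, 1e-6)
    tr[s] <- sum(ar * as.numeric(us %*% nrm)) / sum(ar)
  }
  peak <- max(tr)
  new("OstiumTrace", times = series@times, velocity = tr,
      peakEmptying = peak, lowWashout = peak < 20)
}

#' Seed passive particles in a sphere around the centerline midpoint
#'
#' Particles are sampled uniformly in the ball centered at the centerline
#' midpoint whose radius is 0.8x the local wall clearance (capped by
#' \code{radius} if given); all initial positions are strictly inside the
#' appendage.
#'
#' @param laaClosed closed (capped) appendage mesh for inside tests.
#' @param centerline the appendage \linkS4class{Centerline}.
#' @param n number of particles (default 500).
#' @param seed RNG seed.
#' @param radius optional seeding radius override (cm); 0 collapses all
#'   particles onto the center point.
#' @return a \linkS4class{ParticleEnsemble} (not yet advected).
#' @export
seedParticles <- function(laaClosed, centerline, n = 500L, seed = 1L,
                          radius = NULL) {
  stopifnot(n >= 1)
  cpt <- as.vector(polylineAt(centerline@points, centerline@L / 2))
  clr <- cpp_closest_points(laaClosed@vertices, laaClosed@faces,
                            matrix(cpt, 1, 3))$dist
  r <- if (is.null(radius)) 0.8 * clr else min(radius, 0.8 * clr)
  if (is.null(radius) && r < 1e-3)
    stop("degenerate lumen: inscribed seeding radius below 1e-3 cm")
  pos <- withSeed(seed, {
    out <- matrix(numeric(0), 0, 3)
    for (tryi in 1:50) {
      need <- n - nrow(out)
      if (need <= 0) break
      d <- matrix(rnorm(3 * need), need, 3)
      d <- d / pmax(rowNorms(d), 1e-300)
      p <- sweep(d * (r * runif(need)^(1 / 3)), 2, cpt, "+")
      ok <- cpp_points_in_mesh(laaClosed@vertices, laaClosed@faces, p,
                               c(0.57731, 0.57718, 0.57760), 0) == 1
      out <- rbind(out, p[ok, , drop = FALSE])
    }
    if (nrow(out) < n) stop("could not place all particles inside the lumen")
    out[seq_len(n), , drop = FALSE]
  })
  new("ParticleEnsemble", positions0 = pos,
      traj = array(numeric(0), c(0, 3, 0)), times = numeric(0),
      status = integer(n))
}

#' Advect particles through a stored flow field series
#'
#' Fourth-order Runge-Kutta through the velocity series (linear in space
#' within each tet, linear in time between snapshots). Particles reaching a
#' wall are projected back inside (a tangential slide); particles exiting
#' through the outlet patch are frozen as departed.
#'
#' @param series a \linkS4class{FlowFieldSeries}.
#' @param particles a \linkS4class{ParticleEnsemble}.
#' @param outletPatch the departing patch name (default \code{"MV"}).
#' @return the ensemble with trajectories and departure status filled in.
#' @export
advectParticles <- function(series, particles, outletPatch = "MV") {
  mesh <- series@mesh
  labs <- as.integer(factor(mesh@boundaryPatch))
  mvCode <- which(levels(factor(mesh@boundaryPatch)) == outletPatch)
  if (length(mvCode) == 0) mvCode <- -1L
  dt <- series@times[2] - series@times[1]
  res <- cpp_advect_particles(mesh@vertices, mesh@tets,
                              as.numeric(series@velocity),
                              dim(series@velocity),
                              particles@positions0, dt,
                              mesh@boundaryFaces, labs,
                              as.integer(mvCode))
  traj <- array(res$traj, c(nrow(particles@positions0), 3,
                            dim(series@velocity)[3]))
  methods::initialize(particles, traj = traj, times = series@times,
                      status = as.integer(res$status))
}

#' Count particles residing in the appendage at cycle ends
#'
#' Membership semantics by default: a particle counts when its instantaneous
#' position lies inside the closed appendage surface (re-entry allowed).
#' \code{"first-exit"} semantics instead drop a particle permanently at its
#' first exit.
#'
#' @param particles an advected \linkS4class{ParticleEnsemble}.
#' @param laaClosed closed appendage mesh defining the region.
#' @param cycleTimes times (s) at which to count (cycle ends).
#' @param mode \code{"membership"} or \code{"first-exit"}.
#' @return integer counts, one per requested time.
#' @export
residenceCounts <- function(particles, laaClosed, cycleTimes,
                            mode = c("membership", "first-exit")) {
  mode <- match.arg(mode)
  if (length(particles@times) == 0) stop("particles have not been advected")
  idx <- vapply(cycleTimes, function(tc)
    which.min(abs(particles@times - tc)), integer(1))
  insideAt <- function(s) {
    p <- matrix(particles@traj[, , s], ncol = 3)
    cpp_points_in_mesh(laaClosed@vertices, laaClosed@faces, p,
                       c(0.57731, 0.57718, 0.57760), 0) == 1
  }
  if (mode == "membership") {
    vapply(idx, function(s) sum(insideAt(s) & TRUE), integer(1))
  } else {
    nT <- length(particles@times)
    everOut <- rep(FALSE, nrow(particles@positions0))
    counts <- integer(length(idx))
    ord <- order(idx)
    lastS <- 1
    for (k in ord) {
      for (s in seq(lastS, idx[k])) everOut <- everOut | !insideAt(s)
      lastS <- idx[k]
      counts[k] <- sum(!everOut)
    }
    counts
  }
}

#' Residual particle fraction
#'
#' @param count particles remaining.
#' @param n0 initial particle count.
#' @return percentage, reported to one decimal.
#' @export
residualFraction <- function(count, n0) {
  if (n0 <= 0) stop("n0 must be positive")
  if (any(count < 0 | count > n0)) stop("count must be in [0, n0]")
  round(100 * count / n0, 1)
}
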