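# Desk-scale incompressible flow solver for the left atrium under atrial
# fibrillation conditions. Chorin-style incremental pressure projection with
# semi-Lagrangian advection (unconditionally stable in the advective CFL),
# implicit viscosity, prescribed pulmonary-vein inflows from the mass-balance
# split, a traction-free mitral outlet with explicit backflow penalization,
# and quasi-static ALE wall motion (the 0.1 mm random displacement is far
# below the cell size, so operators are assembled once on the reference mesh
# and the mesh velocity only enters the advective transport and the flux
# bookkeeping).

#' Blood properties (CGS units)
#'
#' @param rho density in g/cm^3 (default 1.06).
#' @param mu dynamic viscosity in poise (default 0.035).
#' @return list with rho, mu and kinematic viscosity nu.
#' @export
fluidProps <- function(rho = 1.06, mu = 0.035) {
  stopifnot(rho > 0, mu > 0)
  list(rho = rho, mu = mu, nu = mu / rho)
}

#' Mitral valve flowrate waveform under atrial fibrillation
#'
#' A periodic waveform with a systolic plateau at zero (valve closed) and a
#' half-sinusoid E wave; the late atrial-contraction A wave is absent, as in
#' AF. Flowrates are positive out of the atrium (through the open valve).
#'
#' @param period cardiac cycle length T in s (default 0.8 s, 75 bpm).
#' @param QE E-wave peak flowrate in ml/s.
#' @param systoleFrac fraction of the cycle with the valve closed.
#' @param eEndFrac cycle fraction at which the E wave ends.
#' @return list of class \code{MVWaveform}; the implied stroke volume is
#'   \code{QE * 2/pi * (eEndFrac - systoleFrac) * period} ml.
#' @export
mvWaveform <- function(period = 0.8, QE = 160, systoleFrac = 0.35,
                       eEndFrac = 0.95) {
  stopifnot(period > 0, QE >= 0, systoleFrac >= 0, eEndFrac > systoleFrac,
            eEndFrac <= 1)
  structure(list(period = period, QE = QE, systoleFrac = systoleFrac,
                 eEndFrac = eEndFrac,
                 strokeVolume = QE * 2 / pi * (eEndFrac - systoleFrac) * period),
            class = "MVWaveform")
}

#' Evaluate the MV flowrate at time t
#'
#' @param t time(s) in s (vectorized).
#' @param w an \code{\link{mvWaveform}}.
#' @return flowrate(s) in ml/s, >= 0 (0 while the valve is closed).
#' @export
mvFlowrate <- function(t, w) {
  ph <- (t / w$period) %% 1
  open <- ph >= w$systoleFrac & ph < w$eEndFrac
  out <- numeric(length(t))
  out[open] <- w$QE * sin(pi * (ph[open] - w$systoleFrac) /
                            (w$eEndFrac - w$systoleFrac))
  out
}

#' Random wall motion specification for AF
#'
#' Each wall vertex oscillates along its outward normal as
#' \code{a * r_v * sin(2 pi f t)} with an independent uniform(0,1) factor
#' r_v, mimicking the irregular, strongly reduced AF contraction.
#'
#' @param amplitude displacement bound a in cm (default 0.01 cm = 0.1 mm).
#' @param frequency oscillation frequency in Hz (default 4).
#' @param seed RNG seed for the per-vertex factors.
#' @export
wallMotionSpec <- function(amplitude = 0.01, frequency = 4, seed = 1L) {
  stopifnot(amplitude >= 0, frequency > 0)
  structure(list(amplitude = amplitude, frequency = frequency,
                 seed = as.integer(seed)), class = "WallMotionSpec")
}

#' Evaluate the wall displacement field at time t
#'
#' @param t time in s.
#' @param vertices n x 3 vertex coordinates.
#' @param normals n x 3 unit outward normals.
#' @param spec a \code{\link{wallMotionSpec}}.
#' @return n x 3 displacement matrix with row norms <= amplitude.
#' @export
wallDisplacement <- function(t, vertices, normals, spec) {
  rv <- withSeed(spec$seed, runif(nrow(vertices)))
  spec$amplitude * sin(2 * pi * spec$frequency * t) * rv * normals
}

#' Pulmonary-vein flow split by mass balance and sectional area
#'
#' Given the MV flowrate Q^O, the domain volume change dV/dt, the PV
#' sectional areas and the per-PV wall fluxes (all fluxes positive outward),
#' the total PV flux is \code{Qtot = -Q^O - dV/dt} and each PV receives
#' \code{Q_l = (A_l / sum(A)) * Qtot - Qw_l} (the prescribed flux relative
#' to the moving section). The lab-frame balance
#' \code{sum(Q_l + Qw_l) + Q^O + dV/dt} is exactly zero and is returned as
#' attribute \code{residual}.
#'
#' @param QO MV flowrate (ml/s, positive outward).
#' @param dVdt domain volume rate of change (ml/s).
#' @param areas PV sectional areas (cm^2), all positive.
#' @param Qw per-PV wall fluxes (ml/s); default zero.
#' @return per-PV prescribed flowrates (ml/s), with attribute
#'   \code{residual}.
#' @export
pvFlowSplit <- function(QO, dVdt, areas, Qw = numeric(length(areas))) {
  At <- sum(areas)
  if (At <= 0) stop("total PV area must be positive")
  if (any(areas <= 0)) stop("all PV areas must be positive")
  Qtot <- -QO - dVdt
  Ql <- areas / At * Qtot - Qw
  attr(Ql, "residual") <- sum(Ql + Qw) + QO + dVdt
  Ql
}

#' Solver configuration
#'
#' @param dt time step (s), default 0.005.
#' @param nCycles number of cardiac cycles to simulate (>= 1).
#' @param beta backflow penalization coefficient in [0, 1].
#' @param inletProfile \code{"plug"} (flat) or \code{"parabolic"} inlet
#'   velocity profiles (both flux-exact on the discrete patch).
#' @param outlet name of the outlet patch (natural boundary condition).
#' @param advection \code{"bfecc"} (back-and-forth error compensation:
#'   three semi-Lagrangian sweeps, second-order, low numerical diffusion) or
#'   \code{"sl1"} (single first-order sweep).
#' @param nProjIter pressure-projection passes per step (the lumped-mass
#'   correction removes only part of the weak divergence per pass).
#' @param equilibrateOutlet close the residual global mass defect exactly by
#'   a uniform normal-velocity adjustment on the outlet section (the
#'   flow-rate correction customary at natural outlets).
#' @param storePressure keep the pressure history (memory permitting).
#' @export
solverConfig <- function(dt = 0.005, nCycles = 5L, beta = 0.2,
                         inletProfile = c("plug", "parabolic"),
                         outlet = "MV", advection = c("bfecc", "sl1"),
                         nProjIter = 2L,
                         equilibrateOutlet = TRUE, storePressure = FALSE) {
  stopifnot(dt > 0, nCycles >= 1, beta >= 0, beta <= 1, nProjIter >= 1)
  list(dt = dt, nCycles = as.integer(nCycles), beta = beta,
       inletProfile = match.arg(inletProfile), outlet = outlet,
       advection = match.arg(advection),
       nProjIter = as.integer(nProjIter),
       equilibrateOutlet = isTRUE(equilibrateOutlet),
       storePressure = storePressure)
}

# Flux-exact inlet nodal velocities for one patch at a target lab-frame
# flowrate: rim nodes (shared with the wall) keep the wall velocity, the
# interior profile is scaled so the discrete patch flux equals the target.
inletNodalVelocity <- function(pd, mesh, profile) {
  nodes <- pd$nodes
  nb <- pd$normal
  ctr <- colSums(mesh@vertices[nodes, , drop = FALSE] * pd$nodeW[nodes]) /
    sum(pd$nodeW[nodes])
  shape <- if (profile == "parabolic") {
    r2 <- rowSums(sweep(mesh@vertices[nodes, , drop = FALSE], 2, ctr)^2)
    R2 <- pd$area / pi
    pmax(1 - r2 / R2, 0)
  } else rep(1, length(nodes))
  list(nodes = nodes, shape = shape, normal = nb)
}

#' Simulate incompressible flow in a labeled tetrahedral mesh
#'
#' Advances the incompressible Navier-Stokes equations (ALE convective
#' velocity u - w) by semi-Lagrangian advection, an implicit viscous step
#' and an incremental pressure projection. Pulmonary veins (patches
#' \code{PV1..PV4}) receive flux-exact profiles from
#' \code{\link{pvFlowSplit}} driven by the MV waveform; the outlet gets a
#' traction-free natural condition with explicit backflow penalization; the
#' wall moves per the wall-motion spec (quasi-static ALE).
#'
#' Alternatively, \code{inletFlows} prescribes arbitrary per-patch flowrate
#' functions of time (ml/s, positive outward; negative = inflow) for
#' verification problems without the AF boundary system.
#'
#' @param mesh a \linkS4class{TetMesh} with patches \code{WALL}, inlets and
#'   an outlet.
#' @param props \code{\link{fluidProps}}.
#' @param waveform \code{\link{mvWaveform}} driving the PV split (AF mode);
#'   ignored when \code{inletFlows} is given.
#' @param motion \code{\link{wallMotionSpec}} or NULL for rigid walls.
#' @param config \code{\link{solverConfig}}.
#' @param inletFlows optional named list of functions \code{f(t) -> ml/s}.
#' @param tEnd simulation end time; default \code{nCycles * period} (AF
#'   mode) and must be given with \code{inletFlows}.
#' @param verbose print progress every 100 steps.
#' @return a \linkS4class{FlowFieldSeries}.
#' @export
solveFlow <- function(mesh, props = fluidProps(), waveform = mvWaveform(),
                      motion = wallMotionSpec(), config = solverConfig(),
                      inletFlows = NULL, tEnd = NULL, verbose = FALSE) {
  ops <- femOperators(mesh)
  pd <- patchData(mesh)
  nv <- nrow(mesh@vertices)
  dt <- config$dt
  afMode <- is.null(inletFlows)
  if (afMode) {
    need <- c(paste0("PV", 1:4), config$outlet, "WALL")
    if (!all(need %in% names(pd)))
      stop("AF mode needs patches ", paste(need, collapse = ", "))
    inletNames <- paste0("PV", 1:4)
    if (is.null(tEnd)) tEnd <- config$nCycles * waveform$period
  } else {
    inletNames <- names(inletFlows)
    if (is.null(tEnd)) stop("tEnd required with inletFlows")
  }
  outletName <- config$outlet
  nsteps <- round(tEnd / dt)

  # ---- wall motion: separable harmonic extension of the static mode
  bn <- boundaryVertexNormals(mesh)
  wallNodes <- pd$WALL$nodes
  portNodes <- sort(unique(unlist(lapply(pd[setdiff(names(pd), "WALL")],
                                         function(p) p$nodes))))
  dirichletMotion <- sort(unique(c(wallNodes, portNodes)))
  Dmode <- matrix(0, nv, 3)
  if (!is.null(motion) && motion$amplitude > 0) {
    rv <- withSeed(motion$seed, runif(nv))
    wOnly <- setdiff(wallNodes, portNodes) # port caps stay put, rims too
    Dmode[wOnly, ] <- motion$amplitude * rv[wOnly] * bn$normals[wOnly, , drop = FALSE]
    freeM <- setdiff(seq_len(nv), dirichletMotion)
    if (length(freeM)) {
      Kff <- ops$K[freeM, freeM]
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
      rhs <- -ops$K[freeM, dirichletMotion] %*% Dmode[dirichletMotion, , drop = FALSE]
      Dmode[freeM, ] <- as.matrix(Matrix::solve(ch, rhs))
    }
    fHz <- motion$frequency
  } else fHz <- 0
  # static flux coefficients of the motion mode per patch + whole boundary
  modeFlux <- vapply(names(pd), function(p) patchFlux(Dmode, mesh, pd[[p]]),
                     numeric(1))
  dVdtAt <- function(t) if (fHz > 0)
    2 * pi * fHz * cos(2 * pi * fHz * t) * sum(modeFlux) else 0
  QwAt <- function(t, p) if (fHz > 0)
    2 * pi * fHz * cos(2 * pi * fHz * t) * modeFlux[[p]] else 0
  wAt <- function(t) if (fHz > 0)
    2 * pi * fHz * cos(2 * pi * fHz * t) * Dmode else NULL

  # ---- Dirichlet sets and factorizations
  inletNodeSet <- sort(unique(unlist(lapply(pd[inletNames], `[[`, "nodes"))))
  pureWall <- setdiff(wallNodes, inletNodeSet)
  dirV <- sort(unique(c(wallNodes, inletNodeSet)))
  freeV <- setdiff(seq_len(nv), dirV)
  A <- Matrix::Diagonal(x = ops$mL / dt) + props$nu * ops$K
  Aff <- A[freeV, freeV]
  Afd <- A[freeV, dirV]
  chA <- Matrix::Cholesky(Matrix::forceSymmetric(Aff), LDL = FALSE)
  mvNodes <- pd[[outletName]]$nodes
  freeP <- setdiff(seq_len(nv), mvNodes)
  Kpp <- ops$K[freeP, freeP]
  chP <- Matrix::Cholesky(Matrix::forceSymmetric(Kpp), LDL = FALSE)
  # consistent prescribed-flux surface term for the pressure Poisson rhs
  dirFaces <- setdiff(seq_len(nrow(mesh@boundaryFaces)), pd[[outletName]]$faces)
  Sbnd <- boundaryFluxOperator(mesh, dirFaces)

  inletData <- lapply(inletNames, function(p)
    inletNodalVelocity(pd[[p]], mesh, config$inletProfile))
  names(inletData) <- inletNames
  areas <- vapply(pd[inletNames], `[[`, numeric(1), "area")

  loc <- cpp_build_locator(mesh@vertices, mesh@tets)
  U <- matrix(0, nv, 3)
  q <- numeric(nv)
  Uarr <- array(0, c(nv, 3, nsteps + 1))
  Parr <- if (config$storePressure) matrix(0, nv, nsteps + 1) else NULL
  fr <- matrix(0, nsteps, 6 + length(inletNames))
  colnames(fr) <- c("time", inletNames, outletName, "wall", "dVdt",
                    "defectRaw", "defect")
  nbMV <- pd[[outletName]]$normal
  wMV <- pd[[outletName]]$nodeW
  # static outlet equilibration mode: uniform normal velocity on the free
  # outlet nodes, flux-normalized to 1 ml/s
  mvFree <- setdiff(mvNodes, dirV)
  eqMode <- matrix(0, nv, 3)
  if (length(mvFree)) {
    eqMode[mvFree, ] <- matrix(nbMV, length(mvFree), 3, byrow = TRUE)
    eqMode <- eqMode / patchFlux(eqMode, mesh, pd[[outletName]])
  }
  peakQ <- 1e-300

  for (s in seq_len(nsteps)) {
    t1 <- s * dt
    w <- wAt(t1)
    dVdt <- dVdtAt(t1)
    # target lab-frame inlet fluxes
    if (afMode) {
      QO <- mvFlowrate(t1, waveform)
      Qw <- vapply(inletNames, function(p) QwAt(t1, p), numeric(1))
      Qrel <- pvFlowSplit(QO, dVdt, areas, Qw)
      Qlab <- Qrel + Qw
      peakQ <- max(peakQ, abs(QO))
    } else {
      Qlab <- vapply(inletNames, function(p) inletFlows[[p]](t1), numeric(1))
      peakQ <- max(peakQ, sum(abs(Qlab)))
    }
    # semi-Lagrangian advection (convective velocity u - w); BFECC adds a
    # backward sweep and error compensation for second-order accuracy
    conv <- if (is.null(w)) U else U - w
    dep <- mesh@vertices - dt * conv
    if (config$advection == "bfecc") {
      u1 <- cpp_interp_field(loc, U, dep, U, 1e-9)
      u2 <- cpp_interp_field(loc, u1, mesh@vertices + dt * conv, u1, 1e-9)
      usrc <- U + (U - u2) / 2
      # clamp the compensated field to the original range (monotonicity guard)
      for (cc in 1:3) {
        rg <- range(U[, cc])
        usrc[, cc] <- pmin(pmax(usrc[, cc], rg[1]), rg[2])
      }
      Utilde <- cpp_interp_field(loc, usrc, dep, U, 1e-9)
    } else {
      Utilde <- cpp_interp_field(loc, U, dep, U, 1e-9)
    }
    # Dirichlet values at t1
    Ud <- matrix(0, nv, 3)
    if (!is.null(w)) Ud[wallNodes, ] <- w[wallNodes, , drop = FALSE]
    for (p in inletNames) {
      idat <- inletData[[p]]
      pdp <- pd[[p]]
      # the plug covers the whole patch including the rim ring shared with
      # the wall (the usual slip discontinuity of a plug inlet); scaling by
      # the discrete shape flux makes the imposed patch flux exact
      interior <- idat$nodes
      shp <- idat$shape
      Utmp <- matrix(0, nv, 3)
      Utmp[interior, ] <- shp %o% idat$normal
      fShape <- patchFlux(Utmp, mesh, pdp)
      alpha <- Qlab[[p]] / fShape
      Ud[interior, ] <- (alpha * shp) %o% idat$normal
    }
    # backflow penalization at the outlet (explicit, stabilizing only inflow)
    un <- as.numeric(U %*% nbMV)
    bfw <- config$beta * wMV * pmin(un, 0) # <= 0, nonzero on MV nodes only
    # incremental pressure gradient (previous q)
    gqc <- cbind(as.numeric(ops$Gx %*% q), as.numeric(ops$Gy %*% q),
                 as.numeric(ops$Gz %*% q))
    gqn <- as.matrix(ops$Sc %*% gqc)
    rhs <- (ops$mL / dt) * Utilde - gqn + bfw * U
    Ustar <- Ud
    rhsF <- rhs[freeV, , drop = FALSE] - as.matrix(Afd %*% Ud[dirV, , drop = FALSE])
    Ustar[freeV, ] <- as.matrix(Matrix::solve(chA, rhsF))
    # pressure projection, iterated (Richardson on the lumped Schur system)
    U <- Ustar
    for (pit in seq_len(config$nProjIter)) {
      ubar <- as.matrix(ops$Av %*% U) * ops$vol
      bs <- as.numeric(Sbnd$SX %*% U[, 1] + Sbnd$SY %*% U[, 2] +
                         Sbnd$SZ %*% U[, 3])
      b <- (as.numeric(Matrix::t(ops$Gx) %*% ubar[, 1]) +
              as.numeric(Matrix::t(ops$Gy) %*% ubar[, 2]) +
              as.numeric(Matrix::t(ops$Gz) %*% ubar[, 3]) - bs) / dt
      dq <- numeric(nv)
      dq[freeP] <- as.numeric(Matrix::solve(chP, b[freeP]))
      gqc <- cbind(as.numeric(ops$Gx %*% dq), as.numeric(ops$Gy %*% dq),
                   as.numeric(ops$Gz %*% dq))
      gqn <- as.matrix(ops$Sc %*% gqc) / ops$mL
      U[freeV, ] <- U[freeV, ] - dt * gqn[freeV, , drop = FALSE]
      q <- q + dq
    }
    # bookkeeping: lab-frame patch fluxes and the global mass defect
    Ubnd <- U
    if (!is.null(w)) Ubnd[pureWall, ] <- w[pureWall, , drop = FALSE]
    flx <- vapply(names(pd), function(p) patchFlux(Ubnd, mesh, pd[[p]]),
                  numeric(1))
    defectRaw <- sum(flx)
    if (config$equilibrateOutlet && length(mvFree)) {
      U <- U - defectRaw * eqMode
      flx[[outletName]] <- flx[[outletName]] - defectRaw
    }
    defect <- sum(flx)
    fr[s, ] <- c(t1, flx[inletNames], flx[[outletName]],
                 sum(flx[setdiff(names(pd), c(inletNames, outletName))]),
                 dVdt, defectRaw, defect)
    Uarr[, , s + 1] <- U
    if (!is.null(Parr)) Parr[, s + 1] <- q
    if (verbose && s %% 100 == 0)
      message(sprintf("step %d/%d  t=%.3f  defect=%.3g", s, nsteps, t1, defect))
  }
  frd <- as.data.frame(fr)
  frd$peakInflow <- peakQ
  new("FlowFieldSeries", mesh = mesh, times = seq(0, nsteps) * dt,
      velocity = Uarr, pressure = Parr, displacementMode = Dmode,
      motionFrequency = fHz, flowrates = frd)
}
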