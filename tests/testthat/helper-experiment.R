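# The scaled-down directional experiment: two synthetic models sharing one
# template (a short/straight and a long/tortuous appendage), simulated for
# five cardiac cycles at the desk lattice with 500 tracers, repeated over
# three seeds for the stochastic components (wall motion, seeding).
# Computed lazily and cached for the session; used by several acceptance
# checks (problem sizes are stated in the methods vignette).

.exper <- new.env(parent = emptyenv())

deskExperiment <- function(seeds = 1:3) {
  key <- paste0("run_", paste(seeds, collapse = "_"))
  if (!is.null(.exper[[key]])) return(.exper[[key]])
  cfg <- runConfig(nVariants = 2, seed = 101, tier = "desk")
  study <- makeStudySet(2, seed = 101)
  prep <- lapply(1:2, function(i) {
    g <- graftLAA(study$template, study$donors[[i]]$mesh, details = TRUE,
                  apexDirection = cfg$apexDirection)
    tm <- tetrahedralize(capPorts(g$composite), cfg$h)
    donT <- applyTransform(study$donors[[i]]$mesh, g$transform)
    list(tm = tm, laaClosed = capPorts(donT), cl = computeCenterline(donT),
         chi = study$donors[[i]]$truth$chi)
  })
  residual5 <- matrix(NA_real_, length(seeds), 2,
                      dimnames = list(paste0("seed", seeds),
                                      c("straight", "tortuous")))
  counts <- array(NA_integer_, c(length(seeds), 2, 3))
  flowrates1 <- NULL
  for (si in seq_along(seeds)) {
    sd <- seeds[si]
    for (i in 1:2) {
      ff <- solveFlow(prep[[i]]$tm, waveform = cfg$waveform,
                      motion = wallMotionSpec(seed = sd),
                      config = cfg$solver)
      if (si == 1 && i == 1) flowrates1 <- ff@flowrates
      pts <- seedParticles(prep[[i]]$laaClosed, prep[[i]]$cl, n = 500,
                           seed = sd + 1000 * i)
      pts <- advectParticles(ff, pts)
      cnt <- residenceCounts(pts, prep[[i]]$laaClosed,
                             c(3, 4, 5) * cfg$waveform$period)
      counts[si, i, ] <- cnt
      residual5[si, i] <- residualFraction(cnt[3], 500)
    }
  }
  out <- list(residual5 = residual5, counts = counts,
              chi = vapply(prep, `[[`, numeric(1), "chi"),
              flowrates = flowrates1)
  .exper[[key]] <- out
  out
}
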