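test_that("MV waveform: closed in systole, peaks mid-E-wave, integrates to SV", {
  w <- mvWaveform(period = 0.8, QE = 160, systoleFrac = 0.35, eEndFrac = 0.95)
  expect_equal(mvFlowrate(c(0, 0.1, 0.27, 0.77, 0.8), w), c(0, 0, 0, 0, 0))
  tMid <- (0.35 + 0.95) / 2 * 0.8
  expect_equal(mvFlowrate(tMid, w), 160)
  expect_equal(mvFlowrate(tMid + 3 * 0.8, w), 160) # periodic
  tt <- seq(0, 0.8, length.out = 20001)
  sv <- mean(mvFlowrate(tt, w)) * 0.8
  expect_equal(sv, 160 * 2 / pi * (0.95 - 0.35) * 0.8, tolerance = 1e-4)
  expect_true(all(mvFlowrate(tt, w) >= 0))
})

test_that("wall displacement is zero at t=0, bounded, and seed-reproducible", {
  spec <- wallMotionSpec(amplitude = 0.01, frequency = 4, seed = 3)
  set.seed(99)
  v <- matrix(rnorm(300), ncol = 3)
  n <- v / sqrt(rowSums(v^2))
  expect_equal(wallDisplacement(0, v, n, spec), matrix(0, 100, 3))
  dmax <- 0
  for (t in seq(0, 1, by = 0.03)) {
    d <- wallDisplacement(t, v, n, spec)
    dmax <- max(dmax, sqrt(rowSums(d^2)))
  }
  expect_lte(dmax, 0.01 + 1e-12)
  expect_identical(wallDisplacement(0.123, v, n, spec),
                   wallDisplacement(0.123, v, n, spec))
})

test_that("PV split conserves mass exactly with area proportionality", {
  q <- pvFlowSplit(100, 0, rep(1, 4))
  expect_equal(as.numeric(q), rep(-25, 4))
  q2 <- pvFlowSplit(0, -40, rep(2, 4))
  expect_equal(as.numeric(q2), rep(10, 4))
  q3 <- pvFlowSplit(100, 0, c(1, 2, 3, 4))
  expect_equal(as.numeric(q3), c(-10, -20, -30, -40))
  expect_error(pvFlowSplit(1, 0, c(0, 0, 0, 0)), "positive")
  set.seed(1)
  worst <- 0
  for (i in 1:200) {
    Ql <- pvFlowSplit(runif(1, -200, 200), runif(1, -50, 50),
                      runif(4, 0.5, 3), rnorm(4, 0, 5))
    worst <- max(worst, abs(attr(Ql, "residual")))
  }
  expect_lt(worst, 1e-12)
})

test_that("zero forcing keeps the flow identically at rest", {
  tube <- makeCylinderTube(0.3, 1, 16, 7)
  tm <- tetrahedralize(capPorts(tube), 0.11)
  cfg <- solverConfig(dt = 0.01, outlet = "OUTLET")
  ff <- solveFlow(tm, motion = NULL, config = cfg,
                  inletFlows = list(INLET = function(t) 0), tEnd = 0.1)
  expect_lt(max(abs(ff@velocity)), 1e-10)
})

test_that("kinetic energy decays in the unforced limit with backflow on", {
  tube <- makeCylinderTube(0.3, 1, 16, 7)
  tm <- tetrahedralize(capPorts(tube), 0.11)
  cfg <- solverConfig(dt = 0.01, beta = 0.2, outlet = "OUTLET",
                      equilibrateOutlet = FALSE)
  # drive briefly, then cut the inflow and watch the energy decay
  drive <- function(t) if (t < 0.1) -1 else 0
  ff <- solveFlow(tm, motion = NULL, config = cfg,
                  inletFlows = list(INLET = drive), tEnd = 0.5)
  ke <- apply(ff@velocity, 3, function(U) sum(U^2))
  after <- ke[ff@times > 0.12]
  expect_true(all(diff(after) <= 1e-10))
})

test_that("solver output is deterministic for a fixed seed and mesh", {
  study <- makeStudySet(2, seed = 2)
  g <- graftLAA(study$template, study$donors[[1]]$mesh)
  tm <- tetrahedralize(capPorts(g), 0.4)
  cfg <- solverConfig(nCycles = 1)
  w <- mvWaveform()
  m <- wallMotionSpec(seed = 11)
  f1 <- solveFlow(tm, waveform = w, motion = m,
                  config = cfg, tEnd = 0.1)
  f2 <- solveFlow(tm, waveform = w, motion = m,
                  config = cfg, tEnd = 0.1)
  expect_identical(f1@velocity, f2@velocity)
  expect_identical(f1@flowrates, f2@flowrates)
})

test_that("halving the time step barely changes the section-velocity trace", {
  tube <- makeCylinderTube(0.25, 1, 20, 9)
  tm <- tetrahedralize(capPorts(tube), 0.08)
  pulse <- function(t) -1 * sin(pi * t / 0.4)^2
  run <- function(dt) solveFlow(tm, motion = NULL,
                                config = solverConfig(dt = dt, outlet = "OUTLET",
                                                      inletProfile = "parabolic"),
                                inletFlows = list(INLET = pulse), tEnd = 0.4)
  f1 <- run(0.02)
  f2 <- run(0.01)
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  rim <- cbind(0.25 * cos(th), 0.25 * sin(th), 0.5)
  tr1 <- ostiumVelocity(f1, rim, c(0, 0, 0.1))@velocity[-1]
  tr2full <- ostiumVelocity(f2, rim, c(0, 0, 0.1))
  tr2 <- tr2full@velocity[match(round(f1@times[-1], 10),
                                round(f2@times, 10))]
  expect_lt(sqrt(sum((tr1 - tr2)^2) / sum(tr2^2)), 0.10)
})
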