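# Analytic linear velocity fields have exact P1 cell gradients, so the
# Q-criterion values below are exact up to roundoff.

test_that("Q-criterion reproduces the analytic suite exactly", {
  tm <- boxTetMesh(1, 0.25)
  v <- tm@vertices
  qOf <- function(U, conv = "printed") qCriterion(tm, U = U, convention = conv)@values
  expect_lt(max(abs(qOf(matrix(1, nrow(v), 3)))), 1e-10)         # uniform
  om <- 2.5
  rot <- cbind(-om * v[, 2], om * v[, 1], 0)
  expect_lt(max(abs(qOf(rot) - 4 * om^2)), 1e-8)                 # solid rotation
  al <- 1.7
  strain <- cbind(al * v[, 1], -al * v[, 2], 0)
  expect_lt(max(abs(qOf(strain) + 4 * al^2)), 1e-8)              # pure strain
  shear <- cbind(3 * v[, 2], 0, 0)
  expect_lt(max(abs(qOf(shear))), 1e-8)                          # simple shear
})

test_that("printed convention is exactly 4x the standard one", {
  tm <- boxTetMesh(1, 0.25)
  set.seed(5)
  U <- matrix(rnorm(nrow(tm@vertices) * 3), ncol = 3)
  qp <- qCriterion(tm, U = U, convention = "printed")@values
  qs <- qCriterion(tm, U = U, convention = "standard")@values
  expect_equal(qp, 4 * qs, tolerance = 1e-12)
})

test_that("Q is Galilean invariant", {
  tm <- boxTetMesh(1, 0.25)
  set.seed(6)
  U <- matrix(rnorm(nrow(tm@vertices) * 3), ncol = 3)
  q0 <- qCriterion(tm, U = U)@values
  q1 <- qCriterion(tm, U = sweep(U, 2, c(17, -4, 9), "+"))@values
  expect_lt(max(abs(q1 - q0)), 1e-8 * max(1, max(abs(q0))))
})

test_that("vortex regions follow the sign structure of Q", {
  tm <- boxTetMesh(1, 0.25)
  nC <- nrow(tm@tets)
  allPos <- methods::new("QCriterionField", values = rep(1, nC),
                         convention = "printed", time = 0)
  expect_length(vortexRegions(allPos, tm), 1)
  expect_length(vortexRegions(methods::new("QCriterionField",
                                           values = rep(-1, nC),
                                           convention = "printed", time = 0),
                              tm), 0)
  # two rotation-dominated slabs separated by a strain-dominated gap
  ctr <- (tm@vertices[tm@tets[, 1], ] + tm@vertices[tm@tets[, 2], ] +
            tm@vertices[tm@tets[, 3], ] + tm@vertices[tm@tets[, 4], ]) / 4
  val <- rep(-1, nC)
  val[ctr[, 1] < 0.3] <- 1
  val[ctr[, 1] > 0.7] <- 1
  two <- methods::new("QCriterionField", values = val, convention = "printed",
                      time = 0)
  expect_length(vortexRegions(two, tm), 2)
})

test_that("ostium trace signs follow the emptying convention", {
  tube <- makeCylinderTube(0.4, 2, 16, 9)
  tm <- tetrahedralize(capPorts(tube), 0.14)
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  rim <- cbind(0.4 * cos(th), 0.4 * sin(th), 1) # mid-tube section
  laaPoint <- c(0, 0, 0.2) # pretend the appendage is the z<1 half
  up <- steadySeries(tm, matrix(rep(c(0, 0, 10), each = nrow(tm@vertices)),
                                ncol = 3))
  trUp <- ostiumVelocity(up, rim, laaPoint)
  expect_equal(unique(round(trUp@velocity, 6)), 10)
  dn <- steadySeries(tm, matrix(rep(c(0, 0, -10), each = nrow(tm@vertices)),
                                ncol = 3))
  expect_equal(unique(round(ostiumVelocity(dn, rim, laaPoint)@velocity, 6)), -10)
  z0 <- steadySeries(tm, matrix(0, nrow(tm@vertices), 3))
  trZ <- ostiumVelocity(z0, rim, laaPoint)
  expect_true(trZ@lowWashout)
  expect_equal(trZ@peakEmptying, 0)
})

test_that("particle seeding is inside, centered and reproducible", {
  laa <- makeParametricLAA(laaCurveSpec(rbind(c(0, 0, 0), c(3, 0, 0)),
                                        radius = 0.5))$mesh
  closed <- capPorts(laa)
  cl <- computeCenterline(laa)
  p1 <- seedParticles(closed, cl, n = 500, seed = 4)
  expect_equal(nrow(p1@positions0), 500)
  inside <- atriflow:::cpp_points_in_mesh(closed@vertices, closed@faces,
                                          p1@positions0,
                                          c(0.577, 0.577, 0.578), 0)
  expect_true(all(inside == 1))
  p2 <- seedParticles(closed, cl, n = 500, seed = 4)
  expect_identical(p1@positions0, p2@positions0)
  # radius -> 0 collapses onto the centerline midpoint
  p0 <- seedParticles(closed, cl, n = 1, seed = 4, radius = 0)
  mid <- atriflow:::polylineAt(cl@points, cl@L / 2)
  expect_lt(atriflow:::vnorm(p0@positions0[1, ] - as.vector(mid)), 1e-9)
  # degenerate lumen
  tiny <- methods::initialize(closed, vertices = closed@vertices / 1e3)
  clT <- methods::new("Centerline", points = cl@points / 1e3, L = cl@L / 1e3,
                      D = cl@D / 1e3)
  expect_error(seedParticles(tiny, clT, n = 10, seed = 1), "degenerate lumen")
})

test_that("advection integrates analytic fields accurately", {
  tm <- boxTetMesh(4, 0.5)
  # zero field: no motion
  z <- steadySeries(tm, matrix(0, nrow(tm@vertices), 3), nT = 5, dt = 0.25)
  pts <- methods::new("ParticleEnsemble",
                      positions0 = rbind(c(2, 2, 2), c(1, 1.5, 2.5)),
                      traj = array(numeric(0), c(0, 3, 0)), times = numeric(0),
                      status = integer(2))
  adv <- advectParticles(z, pts, outletPatch = "OUT")
  expect_equal(adv@traj[, , 5], pts@positions0, tolerance = 1e-12)
  # uniform unit field for 1 s: displacement (1,0,0)
  u <- steadySeries(tm, matrix(rep(c(1, 0, 0), each = nrow(tm@vertices)),
                               ncol = 3), nT = 5, dt = 0.25)
  advU <- advectParticles(u, pts, outletPatch = "OUT")
  expect_lt(max(abs(advU@traj[, , 5] - (pts@positions0 +
                                          matrix(rep(c(1, 0, 0), 2), 2,
                                                 byrow = TRUE)))), 1e-6)
  # rigid rotation about the box center: closed orbit returns to start
  om <- 2 * pi # one revolution per second
  v <- tm@vertices
  rotU <- cbind(-om * (v[, 2] - 2), om * (v[, 1] - 2), 0)
  nT <- 201
  rot <- steadySeries(tm, rotU, nT = nT, dt = 1 / (nT - 1))
  p1 <- methods::new("ParticleEnsemble", positions0 = rbind(c(2.6, 2, 2)),
                     traj = array(numeric(0), c(0, 3, 0)), times = numeric(0),
                     status = integer(1))
  orb <- advectParticles(rot, p1, outletPatch = "OUT")
  expect_lt(atriflow:::vnorm(orb@traj[1, , nT] - c(2.6, 2, 2)), 1e-3)
})

test_that("residence counts and residual fractions behave", {
  laa <- makeParametricLAA(laaCurveSpec(rbind(c(0, 0, 0), c(3, 0, 0)),
                                        radius = 0.5))$mesh
  closed <- capPorts(laa)
  cl <- computeCenterline(laa)
  pts <- seedParticles(closed, cl, n = 40, seed = 2)
  nT <- 5
  traj <- array(rep(pts@positions0, nT), c(40, 3, nT))
  still <- methods::initialize(pts, traj = traj, times = seq_len(nT) - 1,
                               status = integer(40))
  expect_equal(residenceCounts(still, closed, c(1, 2, 3)), rep(40L, 3))
  # push half of the particles out along +x after t=1
  out <- traj
  out[1:20, 1, 3:5] <- out[1:20, 1, 3:5] + 10
  half <- methods::initialize(pts, traj = out, times = seq_len(nT) - 1,
                              status = integer(40))
  expect_equal(residenceCounts(half, closed, c(1, 4)), c(40L, 20L))
  # membership vs first-exit: a particle that leaves and returns
  back <- traj
  back[1, 1, 3] <- back[1, 1, 3] + 10 # outside at t=2 only
  re <- methods::initialize(pts, traj = back, times = seq_len(nT) - 1,
                            status = integer(40))
  expect_equal(residenceCounts(re, closed, 4), 40L)
  expect_equal(residenceCounts(re, closed, 4, mode = "first-exit"), 39L)
  # fractions: paper-style exact one-decimal reporting
  expect_identical(residualFraction(500, 500), 100)
  expect_identical(residualFraction(0, 500), 0)
  expect_error(residualFraction(1, 0), "positive")
  expect_error(residualFraction(600, 500), "count")
  # invariant to relabeling: counts depend on positions only
  perm <- sample(40)
  reP <- methods::initialize(re, positions0 = re@positions0[perm, ],
                             traj = re@traj[perm, , ], status = integer(40))
  expect_equal(residenceCounts(reP, closed, 4), residenceCounts(re, closed, 4))
})
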