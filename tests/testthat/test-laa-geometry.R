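test_that("tortuosity is L/D - 1 with guarded degenerate input", {
  mk <- function(pts) methods::new("Centerline", points = pts,
                                   L = atriflow:::arclength(pts),
                                   D = atriflow:::vnorm(pts[nrow(pts), ] - pts[1, ]))
  expect_equal(tortuosity(mk(rbind(c(0, 0, 0), c(3, 0, 0)))), 0)
  zig <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(1, 0, 0))
  expect_equal(tortuosity(mk(zig)), sqrt(2) - 1, tolerance = 1e-12)
  th <- seq(0, pi, length.out = 400)
  semi <- cbind(cos(th), sin(th), 0)
  expect_equal(tortuosity(mk(semi)), pi / 2 - 1, tolerance = 1e-4)
})

test_that("orifice metrics match analytic loops and are rigid-invariant", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- cbind(cos(th), sin(th), 0)
  om <- orificeMetrics(circ)
  expect_lt(abs(om$Po - 2 * pi) / (2 * pi), 0.002)
  expect_lt(abs(om$Ao - pi) / pi, 0.005)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  omSq <- orificeMetrics(sq)
  expect_equal(omSq$Po, 4)
  expect_equal(omSq$Ao, 1)
  set.seed(2)
  tilt <- applyTransform(circ, rigidTransform(randomRotation(), c(4, 5, -6)))
  omT <- orificeMetrics(tilt)
  expect_equal(omT$Po, om$Po, tolerance = 1e-9)
  expect_equal(omT$Ao, om$Ao, tolerance = 1e-9)
})

test_that("a self-intersecting rim projection falls back with a message", {
  bow <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  expect_message(orificeMetrics(bow), "self-intersects")
})

test_that("centerline recovers tapered tube ground truth", {
  straight <- makeParametricLAA(laaCurveSpec(rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)),
                                             radius = 0.5, taper = 0.9))
  cl <- computeCenterline(straight$mesh)
  expect_lt(abs(cl@L - 3) / 3, 0.03)
  expect_lt(tortuosity(cl), 0.02)
  phi <- seq(0, pi, length.out = 9)
  arc <- cbind(sin(phi), 1 - cos(phi), 0)
  semi <- makeParametricLAA(laaCurveSpec(arc, radius = 0.25, taper = 0.7))
  clS <- computeCenterline(semi$mesh)
  expect_lt(abs(tortuosity(clS) - (pi / 2 - 1)) / (pi / 2 - 1), 0.10)
})

test_that("a sphere with a tiny rim still yields a defined centerline", {
  sph <- sphereMesh(1, 18, 24)
  # open a small hole around the north pole: remove the top fan
  topFaces <- which(apply(matrix(sph@vertices[sph@faces, 3] > 0.97, ncol = 3),
                          1, all))
  sub <- atriflow:::subsetFaces(sph, setdiff(seq_len(nFaces(sph)), topFaces))
  m <- sub$mesh
  m@portTags <- list(OSTIUM = boundaryLoops(m)[[1]])
  cl <- computeCenterline(m, gridSpacing = 0.12)
  expect_lt(abs(cl@L - 2) / 2, 0.15)
})

test_that("geometry report matches cylinder analytics and scales correctly", {
  spec <- laaCurveSpec(rbind(c(0, 0, 0), c(3, 0, 0)), radius = 0.5,
                       samples = 60, nRing = 28)
  laa <- makeParametricLAA(spec)$mesh
  rep <- geometryReport(laa)
  vAna <- pi * 0.25 * 3 + 2 / 3 * pi * 0.125
  aAna <- 2 * pi * 0.5 * 3 + 2 * pi * 0.25
  expect_lt(abs(rep@V - vAna) / vAna, 0.05)
  expect_lt(abs(rep@As - aAna) / aAna, 0.05)
  expect_lt(abs(rep@Ao - pi * 0.25) / (pi * 0.25), 0.05)
  expect_lt(abs(rep@Po - pi) / pi, 0.05)
  expect_lt(rep@chi, 0.05)
  expect_gte(rep@Po^2, 4 * pi * rep@Ao * (1 - 1e-9)) # isoperimetric
  # uniform scaling: V ~ s^3, areas ~ s^2, lengths ~ s, chi invariant
  s <- 1.7
  big <- methods::initialize(laa, vertices = laa@vertices * s)
  repB <- geometryReport(big)
  expect_equal(repB@V / rep@V, s^3, tolerance = 0.02)
  expect_equal(repB@As / rep@As, s^2, tolerance = 0.02)
  expect_equal(repB@Ao / rep@Ao, s^2, tolerance = 0.02)
  expect_equal(repB@Po / rep@Po, s, tolerance = 0.02)
  expect_equal(repB@L / rep@L, s, tolerance = 0.04)
})

test_that("geometry report is invariant under rigid transforms", {
  spec <- laaCurveSpec(rbind(c(0, 0, 0), c(1.2, 0.6, 0.3), c(2.4, 0.4, 0.9)),
                       radius = 0.45, taper = 0.4)
  laa <- makeParametricLAA(spec)$mesh
  rep <- geometryReport(laa)
  set.seed(9)
  laaT <- applyTransform(laa, rigidTransform(randomRotation(), c(3, -2, 7)))
  repT <- geometryReport(laaT)
  for (slotn in c("V", "As", "Ao", "Po"))
    expect_equal(methods::slot(repT, slotn), methods::slot(rep, slotn),
                 tolerance = 1e-6, info = slotn)
  # centerline runs on a lattice: lengths agree to lattice accuracy
  expect_equal(repT@L, rep@L, tolerance = 0.05)
  expect_equal(repT@chi, rep@chi, tolerance = 0.05)
})
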