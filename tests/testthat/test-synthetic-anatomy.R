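test_that("swept-tube ground truth matches analytic curves", {
  straight <- makeParametricLAA(laaCurveSpec(rbind(c(0, 0, 0), c(3, 0, 0)),
                                             radius = 0.5))
  expect_equal(straight$truth$chi, 0)
  expect_equal(straight$truth$L, 3)
  # semicircular arc radius 1: L = pi, D = 2, chi = pi/2 - 1
  phi <- seq(0, pi, length.out = 9)
  arc <- cbind(sin(phi), 1 - cos(phi), 0)
  semi <- makeParametricLAA(laaCurveSpec(arc, radius = 0.25))
  expect_lt(abs(semi$truth$chi - (pi / 2 - 1)), 0.01)
  # straight cylinder volume oracle at fine sampling
  cyl <- makeParametricLAA(laaCurveSpec(rbind(c(0, 0, 0), c(3, 0, 0)),
                                        radius = 0.5, samples = 120,
                                        nRing = 48))
  vCap <- pi * 0.25 * 3 + 2 / 3 * pi * 0.5^3
  expect_lt(abs(enclosedVolume(capPorts(cyl$mesh)) - vCap) / vCap, 0.03)
})

test_that("tube meshes are closed by the ostium cap alone and refine to analytic", {
  spec <- function(s, m) laaCurveSpec(rbind(c(0, 0, 0), c(3, 0, 0)),
                                      radius = 0.5, samples = s, nRing = m)
  coarse <- makeParametricLAA(spec(20, 10))
  fine <- makeParametricLAA(spec(40, 20))
  expect_length(boundaryLoops(coarse$mesh), 1)
  vAna <- coarse$truth$V
  errC <- abs(enclosedVolume(capPorts(coarse$mesh)) - vAna) / vAna
  errF <- abs(enclosedVolume(capPorts(fine$mesh)) - vAna) / vAna
  # roughly second-order: doubling the resolution cuts the error ~4x
  expect_lt(errF, errC / 2.5)
  aC <- abs(surfaceArea(coarse$mesh) - coarse$truth$As) / coarse$truth$As
  aF <- abs(surfaceArea(fine$mesh) - fine$truth$As) / fine$truth$As
  expect_lt(aF, aC / 2.5)
})

test_that("self-intersecting tubes are rejected with a diagnostic", {
  hairpin <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.2, 0.15, 0), c(0.2, 0.3, 0),
                   c(-0.8, 0.3, 0))
  expect_error(makeParametricLAA(laaCurveSpec(hairpin, radius = 0.4)),
               "self-intersects")
})

test_that("template atrium has six tagged ports and sane volume", {
  spec <- templateLASpec()
  tpl <- makeTemplateLA(spec)
  expect_length(boundaryLoops(tpl), 6)
  expect_setequal(names(portTags(tpl)),
                  c(paste0("PV", 1:4), "MV", "OSTIUM"))
  # enclosed volume close to ellipsoid + port tube add-ons
  vEll <- 4 / 3 * pi * prod(spec$semiAxes)
  vTubes <- sum(vapply(spec$ports, function(p) pi * p$radius^2 * p$length,
                       numeric(1)))
  v <- enclosedVolume(capPorts(tpl))
  expect_lt(abs(v - (vEll + vTubes)) / (vEll + vTubes), 0.05)
})

test_that("degenerate and overlapping ports are rejected", {
  expect_error(templateLASpec(ostiumPort = list(direction = c(-0.55, -0.1, -0.5),
                                                radius = 0, length = 0.3)),
               "non-positive radius")
  expect_error(templateLASpec(ostiumPort = list(direction = c(0.5, 0.7, 0.5),
                                                radius = 0.72, length = 0.3)),
               "overlap")
})

test_that("study sets span the patient ranges deterministically", {
  s5 <- makeStudySet(5, seed = 1)
  chi <- vapply(s5$donors, function(d) d$truth$chi, numeric(1))
  L <- vapply(s5$donors, function(d) d$truth$L, numeric(1))
  expect_true(all(diff(chi) > 0))
  expect_lte(min(chi), 0.03); expect_gte(max(chi), 0.46)
  expect_lte(min(L), 2.3); expect_gte(max(L), 3.5)
  s2 <- makeStudySet(2, seed = 1)
  expect_lt(s2$donors[[1]]$truth$chi, 0.1)
  expect_gt(s2$donors[[2]]$truth$chi, 0.3)
  s2b <- makeStudySet(2, seed = 1)
  expect_identical(s2$donors[[2]]$mesh@vertices, s2b$donors[[2]]$mesh@vertices)
  s2c <- makeStudySet(2, seed = 2)
  expect_false(identical(s2$donors[[2]]$mesh@vertices,
                         s2c$donors[[2]]$mesh@vertices))
})
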