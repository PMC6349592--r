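test_that("sphere SDF matches chord-length bounds with low variation", {
  sph <- sphereMesh(1, 14, 20)
  sdf <- computeSDF(sph, coneHalfAngle = pi / 3, nRays = 30, seed = 1)
  expect_true(all(sdf@values <= 2 + 1e-6))
  expect_true(all(sdf@values >= 2 * cos(pi / 3) - 1e-6))
  expect_lt(sd(sdf@values) / mean(sdf@values), 0.05)
})

test_that("long cylinder lateral SDF is close to the diameter", {
  cyl <- capPorts(makeCylinderTube(0.5, 6, 18, 25))
  sdf <- computeSDF(cyl, nRays = 30, seed = 2)
  ctr <- (cyl@vertices[cyl@faces[, 1], ] + cyl@vertices[cyl@faces[, 2], ] +
            cyl@vertices[cyl@faces[, 3], ]) / 3
  lateral <- abs(ctr[, 3] - 3) < 2 & ctr[, 1]^2 + ctr[, 2]^2 > 0.2
  expect_lt(abs(median(sdf@values[lateral]) - 1), 0.1)
})

test_that("zero cone angle degenerates to the antipodal ray", {
  sph <- sphereMesh(1, 10, 14)
  sdf0 <- computeSDF(sph, coneHalfAngle = 0, nRays = 5, seed = 1)
  # all rays collapse onto the axis: value = single antipodal ray length,
  # checked against the independent caster
  orc <- oracleSDF(sph, 0, 3)
  expect_lt(max(abs(sdf0@values - orc)), 1e-9)
})

test_that("SDF is pose-invariant and scales linearly", {
  sph <- sphereMesh(1, 10, 14)
  sdf <- computeSDF(sph, nRays = 20, seed = 5)
  set.seed(8)
  tr <- rigidTransform(randomRotation(), c(5, -3, 2))
  sdfT <- computeSDF(applyTransform(sph, tr), nRays = 20, seed = 5)
  expect_lt(max(abs(sdfT@values - sdf@values) / sdf@values), 1e-6)
  big <- methods::initialize(sph, vertices = sph@vertices * 2.5)
  sdfS <- computeSDF(big, nRays = 20, seed = 5)
  expect_lt(max(abs(sdfS@values / sdf@values - 2.5)), 0.05)
})

test_that("compute and brute-force oracle agree on small analytic meshes", {
  sph <- sphereMesh(1, 10, 16) # 288 faces
  mine <- computeSDF(sph, coneHalfAngle = pi / 3, nRays = 200, seed = 1)
  orc <- oracleSDF(sph, pi / 3, 400)
  expect_lt(max(abs(mine@values - orc) / orc), 0.05)
  expect_lt(sd(mine@values) / mean(mine@values), 0.05)
  cyl <- capPorts(makeCylinderTube(0.5, 2, 12, 9)) # ~240 faces
  mineC <- computeSDF(cyl, coneHalfAngle = pi / 3, nRays = 200, seed = 1)
  orcC <- oracleSDF(cyl, pi / 3, 400)
  expect_lt(median(abs(mineC@values - orcC) / orcC), 0.05)
})

test_that("clustering splits bodies of different diameter", {
  sph <- sphereMesh(1, 12, 18)
  sdf <- computeSDF(sph, nRays = 20, seed = 1)
  lab <- clusterRegions(sdf, sph, kClusters = 2)
  main <- max(table(lab@labels))
  expect_gte(main / length(lab@labels), 0.95)
  expect_equal(lab@chamberId, atriflow:::modeInt(lab@labels))
  # one-cluster trivia
  lab1 <- clusterRegions(sdf, sph, kClusters = 1, spatialWeight = 0)
  expect_equal(unique(lab1@labels), 1L)
  expect_error(clusterRegions(sdf, sph, kClusters = 10 * length(sdf@values)),
               "distinct")
})

test_that("two bodies bridged by a thin neck get different labels", {
  # dumbbell: wide bulb - thin neck - narrow bulb, as one swept tube
  prof <- function(s) {
    r <- numeric(length(s))
    r[s <= 0.38] <- 0.9
    bl <- s > 0.38 & s < 0.62
    r[bl] <- 0.9 + (0.5 - 0.9) * (s[bl] - 0.38) / 0.24
    r[s >= 0.62] <- 0.5
    r - 0.32 * exp(-((s - 0.5) / 0.07)^2) # neck dip
  }
  tube <- makeParametricLAA(laaCurveSpec(rbind(c(0, 0, 0), c(6, 0, 0)),
                                         radius = prof, samples = 60,
                                         nRing = 18))$mesh
  body <- capPorts(tube)
  sdf <- computeSDF(body, nRays = 30, seed = 3)
  lab <- clusterRegions(sdf, body, kClusters = 3)
  ctr <- (body@vertices[body@faces[, 1], ] + body@vertices[body@faces[, 2], ] +
            body@vertices[body@faces[, 3], ]) / 3
  l1 <- atriflow:::modeInt(lab@labels[ctr[, 1] < 2])
  l2 <- atriflow:::modeInt(lab@labels[ctr[, 1] > 4])
  expect_false(l1 == l2)
})
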