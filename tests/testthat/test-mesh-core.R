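test_that("area and enclosed volume match analytic solids", {
  cube <- unitCubeMesh()
  expect_equal(surfaceArea(cube), 6)
  expect_equal(enclosedVolume(cube), 1)
  sph <- sphereMesh(1, 32, 48)
  expect_lt(abs(enclosedVolume(sph) - 4 * pi / 3) / (4 * pi / 3), 0.01)
  expect_lt(abs(surfaceArea(sph) - 4 * pi) / (4 * pi), 0.01)
})

test_that("volume is translation-invariant and area rigid-invariant", {
  sph <- sphereMesh(1, 12, 18)
  v0 <- enclosedVolume(sph)
  shift <- methods::initialize(sph, vertices = sweep(sph@vertices, 2,
                                                     c(123.4, -56.7, 89)))
  expect_lt(abs(enclosedVolume(shift) - v0) / v0, 1e-9)
  set.seed(3)
  tr <- rigidTransform(randomRotation(), c(2, -1, 5))
  expect_equal(surfaceArea(applyTransform(sph, tr)), surfaceArea(sph),
               tolerance = 1e-9)
})

test_that("boundary loops are found and ordered", {
  expect_length(boundaryLoops(unitCubeMesh()), 0)
  cyl <- makeCylinderTube(0.3, 1, 16, 5)
  expect_length(boundaryLoops(cyl), 2)
  laa <- makeParametricLAA(laaCurveSpec(rbind(c(0, 0, 0), c(2, 0, 0)),
                                        radius = 0.4))$mesh
  expect_length(boundaryLoops(laa), 1)
  expect_error(enclosedVolume(cyl), "2 open boundary loop")
})

test_that("capping all ports closes every boundary loop", {
  cyl <- makeCylinderTube(0.3, 1, 16, 5)
  capped <- capPorts(cyl)
  expect_length(boundaryLoops(capped), 0)
  expect_lt(abs(enclosedVolume(capped) - pi * 0.09) / (pi * 0.09), 0.03)
})

test_that("laplacian smoothing: identity at 0 iterations, denoises, shrinks", {
  # fine sphere so curvature shrinkage stays below the injected noise
  sph <- sphereMesh(1, 40, 60)
  expect_equal(laplacianSmooth(sph, 0)@vertices, sph@vertices)
  set.seed(11)
  noisy <- methods::initialize(sph, vertices = sph@vertices *
                                 (1 + 0.02 * rnorm(nrow(sph@vertices))))
  err0 <- max(abs(sqrt(rowSums(noisy@vertices^2)) - 1))
  sm <- laplacianSmooth(noisy, 10, 0.5)
  err1 <- max(abs(sqrt(rowSums(sm@vertices^2)) - 1))
  expect_lt(err1, err0)
  cube <- unitCubeMesh()
  expect_lt(enclosedVolume(laplacianSmooth(cube, 5, 0.5)), 1)
})

test_that("mesh formats round-trip; unknown extension errors", {
  cube <- unitCubeMesh()
  for (ext in c("stl", "ply", "off", "vtk")) {
    p <- tempfile(fileext = paste0(".", ext))
    writeMesh(cube, p)
    back <- readMesh(p)
    expect_equal(nFaces(back), 12, info = ext)
    expect_equal(enclosedVolume(back), 1, tolerance = 1e-6, info = ext)
    if (ext != "stl") expect_equal(back@faces, cube@faces, info = ext)
  }
  pb <- tempfile(fileext = ".stl")
  writeMesh(cube, pb, binary = TRUE)
  expect_equal(enclosedVolume(readMesh(pb)), 1, tolerance = 1e-6)
  expect_error(writeMesh(cube, tempfile(fileext = ".obj")), "unsupported")
  expect_error(readMesh(tempfile(fileext = ".xyz")), "unsupported")
})

test_that("PLY and VTK carry per-face labels through a round trip", {
  cube <- unitCubeMesh()
  cube@faceLabels <- rep(c(0L, 1L), 6)
  for (ext in c("ply", "vtk")) {
    p <- tempfile(fileext = paste0(".", ext))
    writeMesh(cube, p)
    expect_equal(readMesh(p)@faceLabels, cube@faceLabels, info = ext)
  }
})
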