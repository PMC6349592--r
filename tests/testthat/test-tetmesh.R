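test_that("unit cube tetrahedralizes exactly", {
  tm <- tetrahedralize(unitCubeMesh(), 0.26)
  expect_lt(abs(sum(atriflow:::tetVolumes(tm@vertices, tm@tets)) - 1), 1e-6)
  expect_true(all(atriflow:::tetVolumes(tm@vertices, tm@tets) > 0))
})

test_that("sphere volume converges with the lattice and boundary snaps on", {
  sph <- sphereMesh(1, 28, 40)
  vref <- enclosedVolume(sph)
  tm <- tetrahedralize(sph, 0.14)
  vt <- sum(atriflow:::tetVolumes(tm@vertices, tm@tets))
  expect_lt(abs(vt - vref) / vref, 0.05)
  # snapped boundary vertices sit on (or very near) the input surface
  bvs <- unique(as.integer(tm@boundaryFaces))
  d <- atriflow:::cpp_closest_points(sph@vertices, sph@faces,
                                     tm@vertices[bvs, , drop = FALSE])$dist
  expect_lt(median(d), 0.03)
})

test_that("non-watertight input is rejected", {
  cyl <- makeCylinderTube(0.3, 1, 16, 5)
  expect_error(tetrahedralize(cyl, 0.1), "not watertight")
})

test_that("composite atrium meshes with all patches present", {
  study <- makeStudySet(2, seed = 3)
  comp <- graftLAA(study$template, study$donors[[1]]$mesh)
  tm <- tetrahedralize(capPorts(comp), 0.36)
  expect_setequal(unique(tm@boundaryPatch),
                  c("WALL", paste0("PV", 1:4), "MV"))
  expect_gt(nrow(tm@tets), 5000)
})
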