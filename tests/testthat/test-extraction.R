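# Automatic LAA isolation on synthetic composites with known ground truth.

makeComposite <- function(seed = 3) {
  study <- makeStudySet(2, seed = seed)
  don <- study$donors[[2]]$mesh
  g <- graftLAA(study$template, don, details = TRUE)
  nT <- nrow(study$template@vertices)
  list(study = study, graft = g,
       donorFaces = nrow(study$template@faces) + seq_len(nrow(don@faces)))
}

test_that("identifyLAA recovers the grafted appendage faces", {
  cmp <- makeComposite()
  comp <- cmp$graft$composite
  sdf <- computeSDF(capPorts(comp), nRays = 30, seed = 1)
  # the capped mesh shares the face order of the composite for original faces
  lab <- clusterRegions(sdf, capPorts(comp), kClusters = 4)
  fs <- identifyLAA(lab, capPorts(comp))
  truth <- cmp$donorFaces
  overlap <- length(intersect(fs, truth)) / length(truth)
  expect_gte(overlap, 0.9)

  # a hint on the chamber resolves to the chamber region and errors
  expect_error(identifyLAA(lab, capPorts(comp), hint = c(0, 0, 0)),
               "chamber")
})

test_that("no appendage candidate without an LAA", {
  tpl <- makeTemplateLA(templateLASpec(ostiumPort = NULL, nTheta = 26, nPhi = 40))
  closed <- capPorts(tpl)
  sdf <- computeSDF(closed, nRays = 25, seed = 1)
  lab <- clusterRegions(sdf, closed, kClusters = 2)
  expect_error(identifyLAA(lab, closed), "no appendage candidate")
})

test_that("extractSubmesh yields one ostium loop each and restores exactly", {
  cmp <- makeComposite()
  comp <- cmp$graft$composite
  parts <- extractSubmesh(comp, cmp$donorFaces)
  expect_length(boundaryLoops(parts$laa), 1)
  expect_true("OSTIUM" %in% names(portTags(parts$laa)))
  expect_true("OSTIUM" %in% names(portTags(parts$remainder)))
  # re-stitching the two parts reproduces the composite vertex set exactly
  allv <- rbind(parts$laa@vertices, parts$remainder@vertices)
  key <- paste(allv[, 1], allv[, 2], allv[, 3])
  keyC <- paste(comp@vertices[, 1], comp@vertices[, 2], comp@vertices[, 3])
  expect_true(all(keyC %in% key))
  expect_error(extractSubmesh(comp, c(1, nrow(comp@faces))),
               "not edge-connected")
})
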