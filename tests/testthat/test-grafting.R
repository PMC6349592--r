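test_that("ICP recovers random rigid and scaled transforms", {
  set.seed(21)
  # a rim-like ellipse with noise in 3D
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  A <- cbind(1.2 * cos(th), 0.8 * sin(th), 0.1 * sin(2 * th))
  expect_lt(icpAlign(A, A)$rms, 1e-12)
  for (rep in 1:3) {
    R <- randomRotation(); tr <- rnorm(3)
    B <- sweep(A %*% t(R), 2, tr, "+")
    fit <- icpAlign(A, B)
    expect_lt(fit$rms, 1e-6)
    # recovered transform maps A onto the point set B
    AT <- applyTransform(A, fit$transform)
    d2 <- outer(rowSums(AT^2), rowSums(B^2), "+") - 2 * AT %*% t(B)
    expect_lt(max(sqrt(pmax(apply(d2, 1, min), 0))), 1e-5)
  }
  R <- randomRotation()
  B <- sweep(1.5 * A %*% t(R), 2, c(1, 2, 3), "+")
  fit <- icpAlign(A, B, withScale = TRUE)
  expect_lt(abs(fit$transform@scale - 1.5), 1e-6)
  expect_lt(fit$rms, 1e-9)
})

test_that("ICP rms is non-increasing and collinear sets are rejected", {
  set.seed(4)
  A <- matrix(rnorm(300), ncol = 3)
  B <- sweep(A %*% t(randomRotation()), 2, c(1, 0, -2), "+")
  fit <- icpAlign(A, B)
  expect_true(all(diff(fit$rmsHistory) <= 1e-9))
  line <- cbind(seq_len(10), 2 * seq_len(10), -seq_len(10))
  expect_error(icpAlign(line, B), "collinear")
  expect_error(icpAlign(A, line), "collinear")
})

test_that("graft closes the composite and restores the cut volume", {
  study <- makeStudySet(2, seed = 5)
  don <- study$donors[[1]]$mesh
  g <- graftLAA(study$template, don, details = TRUE)
  comp <- g$composite
  loops <- boundaryLoops(comp)
  expect_length(loops, 5) # PV1..4 + MV only
  expect_setequal(names(portTags(comp)), c(paste0("PV", 1:4), "MV"))
  vComp <- enclosedVolume(capPorts(comp))
  # cut the appendage back out and re-graft with the identity transform
  nT <- nrow(study$template@faces)
  donorFaces <- nT + seq_len(nrow(don@faces))
  parts <- extractSubmesh(comp, donorFaces)
  re <- graftLAA(parts$remainder, parts$laa, transform = rigidTransform())
  vRe <- enclosedVolume(capPorts(re))
  expect_lt(abs(vRe - vComp) / vComp, 0.01)
})

test_that("composite volume decomposes into template-minus-LAA plus donor", {
  study <- makeStudySet(2, seed = 5)
  don <- study$donors[[1]]$mesh
  g <- graftLAA(study$template, don, details = TRUE)
  vComp <- enclosedVolume(capPorts(g$composite))
  vTpl <- enclosedVolume(capPorts(study$template))
  donT <- applyTransform(don, g$transform)
  vDon <- enclosedVolume(capPorts(donT))
  expect_lt(abs(vComp - (vTpl + vDon)) / vComp, 0.02)
})

test_that("forcing the wrong rim orientation raises the seam error", {
  study <- makeStudySet(2, seed = 5)
  don <- study$donors[[1]]$mesh
  g <- graftLAA(study$template, don, details = TRUE)
  # exactly one of the two forced orientations is the twisted one
  errs <- vapply(c("keep", "flip"), function(o)
    inherits(tryCatch(graftLAA(study$template, don, transform = g$transform,
                               orientation = o),
                      error = function(e) e), "error"), logical(1))
  expect_equal(sum(errs), 1L)
  failing <- names(errs)[errs]
  expect_error(graftLAA(study$template, don, transform = g$transform,
                        orientation = failing),
               "self-intersecting seam")
})

test_that("model sets share the template chamber outside the seam band", {
  study <- makeStudySet(2, seed = 6)
  donors <- lapply(study$donors, `[[`, "mesh")
  set <- buildModelSet(study$template, donors)
  expect_length(set, 2)
  expect_length(buildModelSet(study$template, list()), 0)
  # chamber vertices far from the ostium are bitwise identical
  rim <- study$template@vertices[study$template@portTags$OSTIUM, , drop = FALSE]
  ctr <- colMeans(rim)
  nT <- nrow(study$template@vertices)
  far <- which(sqrt(rowSums(sweep(study$template@vertices, 2, ctr)^2)) > 1.5)
  expect_identical(set[[1]]@vertices[far, ], set[[2]]@vertices[far, ])
})
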