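test_that("threshold descent reproduces hand-executed 1D toys", {
  gs <- c(7, 3, 3)
  vol <- array(-1000, gs)
  mask <- array(FALSE, gs)
  vol[2:6, 2, 2] <- c(500, 400, 300, 200, 100)
  mask[2:6, 2, 2] <- TRUE
  ofm <- computeOrderedFractionMap(CTVolume(vol), mask, closingRadiusMM = 0)
  expect_equal(fractionMap(ofm)[2:6, 2, 2], c(0.2, 0.4, 0.6, 0.8, 1.0))

  # a tie: two voxels share the final inclusion step and its fraction
  vol[2:6, 2, 2] <- c(500, 100, 300, 200, 100)
  ofm <- computeOrderedFractionMap(CTVolume(vol), mask, closingRadiusMM = 0)
  expect_equal(fractionMap(ofm)[2:6, 2, 2], c(0.2, 1.0, 0.4, 0.6, 1.0))
  # fractions are non-decreasing in the step index
  st <- stepIndexMap(ofm)[mask]
  fr <- fractionMap(ofm)[mask]
  expect_true(all(diff(fr[order(st)]) >= 0))
})

test_that("closing-disabled ordering equals the sort oracle on random grids", {
  set.seed(42)
  for (i in 1:40) {
    g <- randomGrid(shape = sample(4:10, 3, replace = TRUE))
    ofm <- computeOrderedFractionMap(g$vol, g$mask, closingRadiusMM = 0)
    expect_equal(fractionMap(ofm), oracleFractionMap(ctData(g$vol), g$mask))
  }
})

test_that("a constant-HU mask degenerates to one tie group with a warning", {
  vol <- array(100, c(6, 6, 6))
  mask <- array(TRUE, c(6, 6, 6))
  expect_warning(ofm <- computeOrderedFractionMap(CTVolume(vol), mask),
                 "degenerate")
  expect_true(all(fractionMap(ofm)[mask] == 1))
  lay <- quartileMasks(ofm)
  counts <- tabulate(layerLabels(lay)[layerLabels(lay) > 0], 4)
  expect_equal(counts, c(0, 0, 0, 216))
  expect_equal(unname(lay@tieSpillover), c(216, 216, 216))
  # the Q1 scheme is then empty and downstream rendering refuses it
  expect_error(renderMIP(CTVolume(vol), combineLayers(lay, "Q1"),
                         makeViewSet()[1, ]), "empty")
})

test_that("input validation rejects bad masks and steps", {
  vol <- CTVolume(array(0, c(5, 5, 5)))
  expect_error(computeOrderedFractionMap(vol, array(FALSE, c(5, 5, 5))),
               "empty")
  expect_error(computeOrderedFractionMap(vol, array(TRUE, c(4, 5, 5))),
               "grids differ")
  expect_error(computeOrderedFractionMap(vol, array(TRUE, c(5, 5, 5)),
                                         huStep = 0.5), "huStep")
})

test_that("quartile masks partition the mask with balanced layers", {
  set.seed(7)
  # 100 distinct-HU voxels -> exactly 25 per layer
  gs <- c(10, 10, 4)
  vol <- array(sample(1:400, prod(gs)), gs)
  mask <- array(FALSE, gs); mask[, , 2:3] <- TRUE
  n <- sum(mask)
  vol[!mask] <- -1000
  ofm <- computeOrderedFractionMap(CTVolume(vol), mask, closingRadiusMM = 0)
  lay <- quartileMasks(ofm)
  counts <- tabulate(layerLabels(lay)[layerLabels(lay) > 0], 4)
  expect_equal(counts, rep(n / 4, 4))
  expect_equal(unname(lay@tieSpillover), c(0, 0, 0))

  # partition: disjoint by construction of labels; union = mask
  expect_equal(layerLabels(lay) > 0, mask)
  expect_equal(sum(combineLayers(lay, "full")), n)
  expect_equal(sum(combineLayers(lay, c("Q1", "Q2"))),
               sum(layerMask(lay, "Q1")) + sum(layerMask(lay, "Q2")))
})

test_that("included regions nest monotonically across steps and layers", {
  ph <- generatePhantom(phantomSpec(gridShape = 48, spacingMM = 3, seed = 2))
  full <- maskArray(ph$masks, "left", "full")
  ofm <- computeOrderedFractionMap(ph$volume, full, closingRadiusMM = 4,
                                   huStep = 5)
  st <- stepIndexMap(ofm)
  smax <- max(st, na.rm = TRUE)
  checkpoints <- unique(round(seq(0, smax, length.out = 6)))
  prev <- NULL
  for (s in checkpoints) {
    cur <- !is.na(st) & st <= s
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }
  lay <- quartileMasks(ofm)
  q12 <- combineLayers(lay, c("Q1", "Q2"))
  expect_true(all(q12[layerMask(lay, "Q1")]))
  expect_equal(combineLayers(lay, "full"), array(full, dim(full)))
})

test_that("rerunning the descent on identical inputs is bit-identical", {
  g <- withr::with_seed(3, randomGrid(c(9, 9, 9)))
  a <- computeOrderedFractionMap(g$vol, g$mask, closingRadiusMM = 2)
  b <- computeOrderedFractionMap(g$vol, g$mask, closingRadiusMM = 2)
  expect_identical(fractionMap(a), fractionMap(b))
  expect_identical(stepIndexMap(a), stepIndexMap(b))
})

test_that("closing absorbs enclosed low-attenuation voxels at the bright step", {
  # a bright cube with a single dark voxel inside: with closing, the
  # enclosed voxel is absorbed at the cube's step, not at its own HU
  gs <- c(15, 15, 11)
  vol <- array(-900, gs)
  mask <- array(FALSE, gs)
  mask[3:13, 3:13, 2:10] <- TRUE
  vol[5:11, 5:11, 4:8] <- 300
  vol[8, 8, 6] <- -900
  noClose <- computeOrderedFractionMap(CTVolume(vol), mask,
                                       closingRadiusMM = 0)
  close3 <- computeOrderedFractionMap(CTVolume(vol), mask,
                                      closingRadiusMM = 3)
  expect_equal(stepIndexMap(close3)[8, 8, 6], 0L)
  expect_equal(fractionMap(close3)[8, 8, 6], fractionMap(close3)[5, 5, 4])
  expect_lt(fractionMap(close3)[8, 8, 6], fractionMap(noClose)[8, 8, 6])
})

test_that("combineLayers validates schemes and the initial role", {
  g <- withr::with_seed(5, randomGrid(c(8, 8, 8)))
  lay <- quartileMasks(computeOrderedFractionMap(g$vol, g$mask,
                                                 closingRadiusMM = 0))
  expect_error(combineLayers(lay, character(0)), "empty")
  expect_error(combineLayers(lay, "Q5"), "scheme")
  expect_error(combineLayers(lay, "initial"), "initial mask")
  ini <- array(FALSE, c(8, 8, 8)); ini[1:2, , ] <- TRUE
  expect_equal(combineLayers(lay, "initial", initial = ini), ini)
  expect_equal(length(maskingSchemes()), 11L)
  expect_setequal(names(maskingSchemes()),
                  c("full", "Q1", "Q1Q2", "Q1Q2Q3", "Q2", "Q2Q3", "Q2Q3Q4",
                    "Q3", "Q3Q4", "Q4", "initial"))
})
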