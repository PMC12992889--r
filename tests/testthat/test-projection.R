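test_that("the default view set has eleven views spanning both axes", {
  v <- makeViewSet()
  expect_equal(nrow(v), 11L)
  expect_equal(sum(v$is_baseline), 1L)
  expect_equal(sum(v$axis == "vertical"), 6L)
  expect_equal(sum(v$axis == "horizontal"), 4L)
  # angle negation mirrors the set onto itself
  neg <- v
  neg$angle_deg <- -neg$angle_deg
  expect_setequal(paste(v$axis, v$angle_deg), paste(neg$axis, neg$angle_deg))
  # duplicates are rejected; empty angle lists give the single AP view
  expect_error(makeViewSet(verticalAngles = c(30, 30)), "duplicate")
  expect_equal(nrow(makeViewSet(numeric(0), numeric(0))), 1L)
})

test_that("view augmentation is seeded, bounded and optional", {
  v <- makeViewSet()
  expect_identical(augmentViews(v, 0, 0, seed = 1), v)
  a1 <- augmentViews(v, 3, 3, seed = 5)
  a2 <- augmentViews(v, 3, 3, seed = 5)
  expect_identical(a1, a2)
  expect_false(identical(a1$angle_deg, v$angle_deg))
  # Monte-Carlo check of the jitter sampler
  d <- unlist(lapply(1:909, function(s)
    augmentViews(v, 3, 3, seed = s)$angle_deg - v$angle_deg))
  expect_gte(min(d), -3)
  expect_lte(max(d), 3)
  expect_lt(abs(mean(d)), 0.1)
})

test_that("a delta phantom renders to the closed-form windowed pixel", {
  gs <- c(224, 16, 224)
  vol <- array(-1024, gs)
  vol[60, 8, 100] <- 300
  mask <- array(TRUE, gs)
  img <- renderMIP(CTVolume(vol, c(1, 1, 1)), mask, makeViewSet()[1, ],
                   window = c(200, 700), outSize = 224L)
  expect_equal(sum(img > 0), 1L)
  expect_equal(max(img), (300 + 150) / 700, tolerance = 1e-12)
  # image row = craniocaudal axis, column = left-right axis
  expect_equal(unname(which(img > 0, arr.ind = TRUE)[1, ]),
               c(100, 60))
})

test_that("the baseline view equals the direct anteroposterior maximum", {
  set.seed(11)
  gs <- c(32, 32, 32)
  vol <- array(round(stats::rnorm(prod(gs), -500, 300)), gs)
  mask <- array(stats::runif(prod(gs)) < 0.4, gs)
  mask[1] <- TRUE
  cvol <- CTVolume(vol, c(1, 1, 1))
  # frame on the whole grid so the pixel raster aligns with the voxel grid
  img <- renderMIP(cvol, mask, makeViewSet()[1, ], window = c(200, 700),
                   outSize = 32L, frameMask = array(TRUE, gs))
  masked <- ifelse(mask, vol, -Inf)
  direct <- t(apply(masked, c(1, 3), max))      # rows = axis 3, cols = axis 1
  direct <- pmin(pmax((direct + 150) / 700, 0), 1)
  direct[!is.finite(direct)] <- 0
  expect_equal(img, direct, tolerance = 1e-12)
})

test_that("projection over a union of regions is the pixelwise maximum", {
  ph <- generatePhantom(phantomSpec(gridShape = 48, spacingMM = 3, seed = 4))
  lay <- computeLayers(ph$volume, ph$masks, "left", huStep = 5)
  views <- makeViewSet()[c(1, 3, 9), ]
  for (pair in list(c("Q1", "Q2"), c("Q3", "Q4"))) {
    a <- combineLayers(lay, pair[1])
    b <- combineLayers(lay, pair[2])
    frame <- maskArray(ph$masks, "left", "full")
    for (k in seq_len(nrow(views))) {
      va <- renderMIP(ph$volume, a, views[k, ], outSize = 64L,
                      frameMask = frame)
      vb <- renderMIP(ph$volume, b, views[k, ], outSize = 64L,
                      frameMask = frame)
      vab <- renderMIP(ph$volume, a | b, views[k, ], outSize = 64L,
                       frameMask = frame)
      expect_lt(max(abs(vab - pmax(va, vb))), 1e-6)
    }
  }
  # hence the full-lung projection dominates every sub-scheme pixelwise
  frame <- maskArray(ph$masks, "left", "full")
  full <- renderMIP(ph$volume, combineLayers(lay, "full"), views[2, ],
                    outSize = 64L, frameMask = frame)
  q2 <- renderMIP(ph$volume, combineLayers(lay, "Q2"), views[2, ],
                  outSize = 64L, frameMask = frame)
  expect_true(all(full - q2 >= -1e-6))
})

test_that("windowing is monotone in voxel HU and bounded in [0, 1]", {
  gs <- c(24, 24, 24)
  set.seed(2)
  vol <- array(round(stats::rnorm(prod(gs), -200, 400)), gs)
  mask <- array(TRUE, gs)
  v <- makeViewSet()[5, ]
  img1 <- renderMIP(CTVolume(vol), mask, v, outSize = 24L)
  vol2 <- vol
  vol2[10:14, 10:14, 10:14] <- vol2[10:14, 10:14, 10:14] + 400
  img2 <- renderMIP(CTVolume(vol2), mask, v, outSize = 24L)
  expect_true(all(img2 - img1 >= -1e-12))
  expect_gte(min(img1), 0)
  expect_lte(max(img1), 1)
})

test_that("a 180-degree vertical rotation mirrors the baseline image", {
  gs <- c(32, 32, 32)
  set.seed(9)
  vol <- array(round(stats::rnorm(prod(gs), -500, 300)), gs)
  mask <- array(FALSE, gs)
  mask[9:24, 9:24, 9:24] <- TRUE
  cvol <- CTVolume(vol, c(1, 1, 1))
  base <- renderMIP(cvol, mask, makeViewSet()[1, ], outSize = 32L)
  flip <- renderMIP(cvol, mask,
                    list(axis = "vertical", angle_deg = 180, inplane_deg = 0),
                    outSize = 32L)
  expect_equal(flip, base[, ncol(base):1], tolerance = 1e-9)
})

test_that("renderMIP rejects empty masks and tiny outputs", {
  vol <- CTVolume(array(0, c(16, 16, 16)))
  v <- makeViewSet()[1, ]
  expect_error(renderMIP(vol, array(FALSE, c(16, 16, 16)), v), "empty")
  expect_error(renderMIP(vol, array(TRUE, c(16, 16, 16)), v, outSize = 4L),
               "outSize")
})

test_that("renderMIPSet packages images with their views", {
  ph <- generatePhantom(phantomSpec(gridShape = 48, spacingMM = 3, seed = 4))
  lay <- computeLayers(ph$volume, ph$masks, "right", huStep = 5)
  ms <- renderMIPSet(ph$volume, combineLayers(lay, "Q1Q2"), makeViewSet(),
                     scheme = "Q1Q2", side = "right", outSize = 64L)
  expect_s4_class(ms, "MIPSet")
  expect_equal(dim(mipImages(ms)), c(64, 64, 11))
  expect_equal(nrow(mipViews(ms)), 11L)
  expect_identical(ms@scheme, "Q1Q2")
})
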