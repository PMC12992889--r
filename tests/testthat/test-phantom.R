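smallSpec <- function(...) phantomSpec(gridShape = 48, spacingMM = 3, ...)

test_that("a no-vessel, no-noise, no-gradient phantom is piecewise constant", {
  sp <- smallSpec(treeParams = list(depth = -1L), noiseSdHU = 0,
                  gradientHU = 0, seed = 1)
  ph <- generatePhantom(sp)
  vals <- unique(as.numeric(ctData(ph$volume)))
  expect_setequal(vals, c(-1024, -850))
  inLung <- maskArray(ph$masks, "left", "full") |
    maskArray(ph$masks, "right", "full")
  expect_true(all(ctData(ph$volume)[inLung] == -850))
  expect_equal(sum(maskArray(ph$masks, "left", "addition")), 0)
})

test_that("phantom generation is bit-identical for a fixed seed", {
  a <- generatePhantom(smallSpec(seed = 7))
  b <- generatePhantom(smallSpec(seed = 7))
  expect_identical(ctData(a$volume), ctData(b$volume))
  expect_identical(maskArray(a$masks, "left", "addition"),
                   maskArray(b$masks, "left", "addition"))
  c <- generatePhantom(smallSpec(seed = 8))
  expect_false(identical(ctData(a$volume), ctData(c$volume)))
})

test_that("vessel-tree attenuation follows the painted decay rule", {
  sp <- smallSpec(noiseSdHU = 0, seed = 2)
  ph <- generatePhantom(sp)
  vol <- ctData(ph$volume)
  full <- maskArray(ph$masks, "left", "full") |
    maskArray(ph$masks, "right", "full")
  # maximum in-mask HU equals the trunk HU; the terminal generation paints
  # rootHU - depth * decay = 400 - 4 * 50 = 200
  expect_equal(max(vol[full]), 400)
  tp <- sp$treeParams
  expect_equal(tp$rootHU - tp$depth * tp$huDecayPerGen, 200)
  # terminal branches paint exactly the terminal attenuation somewhere in
  # the volume, and no vessel paints between the parenchyma ceiling and it
  expect_true(any(abs(vol - 200) < 1e-9))
  expect_false(any(vol[full] > -700 & vol[full] < 200))
  # proximal trunks extend medially outside the lung fields
  expect_gt(sum(maskArray(ph$masks, "left", "addition")), 0)
  expect_gt(sum(maskArray(ph$masks, "right", "addition")), 0)
})

test_that("degenerate geometry is rejected with an explicit message", {
  geom <- list(left = list(center = c(40, 70, 70), semiAxes = c(0, 20, 20)),
               right = list(center = c(100, 70, 70), semiAxes = c(20, 20, 20)))
  expect_error(phantomSpec(lungGeometry = geom), "semi-axes")
  expect_error(phantomSpec(treeParams = list(depth = 2, rootHU = -900),
                           parenchymaHU = -850), "root HU")
})

test_that("injected signal is confined to its target layers", {
  sp <- smallSpec(seed = 5)
  ph <- generatePhantom(sp)
  layers <- lapply(c("left", "right"), function(s)
    computeLayers(ph$volume, ph$masks, s, huStep = 2))
  for (kind in c("dilatation", "tortuosity", "pruning",
                 "mosaic_attenuation")) {
    sig <- signalSpec("Q1", kind, effectMagnitude = 1.5)
    out <- injectSignal(ph$volume, ph$masks, layers, sig, seed = 3)
    delta <- ctData(out) - ctData(ph$volume)
    target <- layerMask(layers[[1]], "Q1") | layerMask(layers[[2]], "Q1")
    expect_equal(max(abs(delta[!target])), 0)
    # magnitude 0 is the identity
    sig0 <- signalSpec("Q1", kind, effectMagnitude = 0)
    out0 <- injectSignal(ph$volume, ph$masks, layers, sig0, seed = 3)
    expect_identical(ctData(out0), ctData(ph$volume))
  }
  expect_error(injectSignal(CTVolume(array(0, c(8, 8, 8))), ph$masks,
                            layers, signalSpec("Q1"), seed = 1),
               "mismatch")
})

test_that("dilatation grows the measured vessel cross-section monotonically", {
  sp <- smallSpec(seed = 6, noiseSdHU = 0)
  ph <- generatePhantom(sp)
  layers <- lapply(c("left", "right"), function(s)
    computeLayers(ph$volume, ph$masks, s, huStep = 2))
  # measure in the plane that contains the left trunk axis and continues
  # into the lung, anchored at an addition-mask point at the hilar entry
  geom <- sp$lungGeometry$left
  pt <- geom$center + c(geom$semiAxes[1] + 3, 0, 0)
  areas <- vapply(c(0, 0.75, 1.5), function(m) {
    vol <- injectSignal(ph$volume, ph$masks, layers,
                        signalSpec("Q1", "dilatation", effectMagnitude = m),
                        seed = 2)
    rec <- measureReference(vol, ph$masks, pt, c(0, 0, 1))
    rec$pa_cross_section_cm2
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_gt(areas[3], areas[1])
})

test_that("cohort bookkeeping: labels, unique ids, determinism", {
  sig <- signalSpec("Q1", "dilatation", effectMagnitude = 1)
  expect_error(generateCohort(0, 5, sig), "nPos")
  coh <- generateCohort(5, 5, sig, smallSpec(), seed = 12)
  expect_equal(nrow(coh$cases), 10L)
  expect_equal(sum(coh$cases$label), 5L)
  expect_false(anyDuplicated(coh$cases$case_id) > 0)
  coh2 <- generateCohort(5, 5, sig, smallSpec(), seed = 12)
  expect_identical(coh$cases, coh2$cases)
  a <- materializeCase(coh, 1)
  b <- materializeCase(coh2, 1)
  expect_identical(ctData(a$volume), ctData(b$volume))
  # per-case jitter: different cases differ
  c2 <- materializeCase(coh, 7)
  expect_false(identical(ctData(a$volume), ctData(c2$volume)))
  expect_equal(a$label, 1L)
  expect_equal(c2$label, 0L)
})
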