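test_that("auroc equals the pair-counting oracle", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), "both classes")
  set.seed(14)
  for (i in 1:30) {
    n <- sample(4:25, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    l <- sample(0:1, n, replace = TRUE)
    if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
    expect_equal(auroc(s, l), oracleAuroc(s, l))
  }
  # scalar-measurement example: {1,2,3} positives vs {2,3,4} negatives
  expect_equal(auroc(c(1, 2, 3, 2, 3, 4), c(1, 1, 1, 0, 0, 0)),
               oracleAuroc(c(1, 2, 3, 2, 3, 4), c(1, 1, 1, 0, 0, 0)))
  # cross-check against an established ROC implementation
  withr::with_seed(8, {
    s <- rnorm(30)
    l <- rep(c(0, 1), 15)
    expect_equal(auroc(s, l),
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))))
  })
})

test_that("fold assignment is a grouped, stratified, seeded partition", {
  ids <- sprintf("p%02d", 1:10)
  labs <- rep(c(0, 1), 5)
  d <- buildCVDesign(ids, labs, cvDesign(nShuffles = 10, nFolds = 5, seed = 4))
  for (s in 1:10) {
    ds <- d[d$shuffle == s, ]
    expect_setequal(ds$case_id, ids)
    expect_equal(as.vector(table(ds$fold)), rep(2L, 5))
    # stratified: every fold holds one case of each class
    for (f in 1:5)
      expect_setequal(labs[match(ds$case_id[ds$fold == f], ids)], c(0, 1))
  }
  # identical seed, identical design (the shared-randomization contract)
  d2 <- buildCVDesign(ids, labs, cvDesign(nShuffles = 10, nFolds = 5, seed = 4))
  expect_identical(d, d2)
  expect_error(buildCVDesign(ids[1:3], labs[1:3], cvDesign(nFolds = 5)),
               "fewer patients")
})

test_that("scheme comparison runs the paired test battery", {
  mk <- function(scheme, a) new("ExperimentResult", scheme = scheme,
                                task = "t", aurocPerShuffle = a,
                                rawAuroc = data.frame(),
                                patientScores = data.frame())
  set.seed(3)
  # ten-shuffle fixture: reference clearly above one scheme, equal to itself
  ref <- 0.8 + rnorm(10, 0, 0.01)
  worse <- ref - 0.1 + rnorm(10, 0, 0.003)   # all differences negative
  results <- list(full = mk("full", ref), low = mk("low", worse))
  cmp <- compareSchemes(results, "full")
  row <- cmp$table[cmp$table$scheme == "low", ]
  # all ten paired differences share a sign: exact two-sided p = 2/2^10
  expect_equal(row$p_vs_reference, 2 / 1024, tolerance = 1e-12)
  expect_equal(row$p_vs_reference, oracleSignedRankP(worse - ref),
               tolerance = 1e-12)
  refRow <- cmp$table[cmp$table$scheme == "full", ]
  expect_true(is.na(refRow$p_vs_reference))
  expect_false(refRow$significant)

  # eleven schemes: ten pairwise rows, Bonferroni threshold 0.05/10
  results11 <- c(list(full = mk("full", ref)),
                 setNames(lapply(1:10, function(k)
                   mk(paste0("s", k), ref - 0.02 * k + rnorm(10, 0, 0.02))),
                   paste0("s", 1:10)))
  cmp11 <- compareSchemes(results11, "full")
  expect_equal(cmp11$bonferroni_threshold, 0.005)
  expect_equal(sum(!is.na(cmp11$table$p_vs_reference)), 10L)
  expect_true(is.finite(cmp11$friedman_p))
  expect_true(is.finite(cmp11$levene_p))
  expect_equal(length(cmp11$shapiro_p), 11L)
  # significance flags do not depend on scheme ordering
  cmpRev <- compareSchemes(rev(results11), "full")
  expect_equal(sort(cmpRev$table$scheme[cmpRev$table$significant]),
               sort(cmp11$table$scheme[cmp11$table$significant]))
})

test_that("the ensemble decision rule is max-lung, threshold, majority", {
  rs <- data.frame(case_id = rep("a", 1), run = 1, left = 0.6, right = 0.2)
  expect_equal(ensembleDecision(rs)$decision, 1L)
  rs5 <- data.frame(case_id = "b", run = 1:5,
                    left = c(0.9, 0.8, 0.1, 0.2, 0.3), right = 0.1)
  expect_equal(ensembleDecision(rs5)$decision, 0L)   # 2 of 5 votes
  rs4 <- data.frame(case_id = "c", run = 1:4,
                    left = c(0.9, 0.8, 0.1, 0.2), right = 0.1)
  expect_warning(dec <- ensembleDecision(rs4), "tie")
  expect_equal(dec$decision, 0L)
  expect_true(dec$tie)
  # adding an all-below-threshold run can never flip negative to positive
  rs4b <- rbind(rs4, data.frame(case_id = "c", run = 5, left = 0.1,
                                right = 0.1))
  expect_equal(ensembleDecision(rs4b)$decision, 0L)
  expect_error(ensembleDecision(transform(rs4, left = NA)), "missing")
})

test_that("reference measurements recover analytic volumes and areas", {
  gs <- c(60, 60, 40)
  vol <- array(-1024, gs)
  addL <- array(FALSE, gs)
  # axis-aligned cylinder, radius 10 mm, along z at (20, 30)
  disc <- outer((seq_len(gs[1]) - 0.5 - 20)^2,
                (seq_len(gs[2]) - 0.5 - 30)^2, "+") <= 100
  for (k in 5:35) addL[, , k] <- disc
  vol[addL] <- 350
  iniL <- array(FALSE, gs); iniL[45:50, 1:10, 1:5] <- TRUE
  iniR <- array(FALSE, gs); iniR[52:58, 1:10, 1:5] <- TRUE
  masks <- LungMaskSet(iniL, iniR, additionLeft = addL, spacing = c(1, 1, 1))
  rec <- measureReference(CTVolume(vol, c(1, 1, 1)), masks,
                          paPoint = c(20, 30, 20), paAxis = c(0, 0, 1))
  expect_equal(rec$added_volume_ml, sum(addL) / 1000)
  expect_equal(rec$pa_cross_section_cm2, pi, tolerance = 0.05)
  # an oblique section through the same cylinder is larger than the
  # perpendicular one; a point off the mask is rejected
  rec45 <- measureReference(CTVolume(vol, c(1, 1, 1)), masks,
                            paPoint = c(20, 30, 20), paAxis = c(0, 1, 1))
  expect_gt(rec45$pa_cross_section_cm2, rec$pa_cross_section_cm2)
  expect_error(measureReference(CTVolume(vol, c(1, 1, 1)), masks,
                                paPoint = c(55, 55, 38), paAxis = c(0, 0, 1)),
               "addition mask")
})

test_that("scalar AUROC bootstrap brackets the point estimate sensibly", {
  withr::with_seed(2, {
    same <- rnorm(40)
    ci1 <- scalarAurocCI(same[1:20], same[21:40], nBoot = 500, seed = 9)
    expect_gt(ci1$ci[2], 0.5)
    expect_lt(ci1$ci[1], 0.5)
    disj <- scalarAurocCI(rnorm(15, 10), rnorm(15, -10), nBoot = 500, seed = 9)
    expect_equal(disj$auroc, 1.0)
    expect_equal(unname(disj$ci), c(1, 1))
    # deterministic for a fixed seed
    rep1 <- scalarAurocCI(same[1:20], same[21:40], nBoot = 500, seed = 9)
    expect_identical(ci1$ci, rep1$ci)
  })
})

test_that("rank-test screens agree with the exact oracle at tiny n", {
  withr::with_seed(6, {
    vals <- c(rnorm(6, 0), rnorm(6, 0.5), rnorm(6, 3))
    groups <- rep(c("a", "b", "c"), each = 6)
    scr <- groupRankTests(vals, groups)
    expect_equal(scr$bonferroni_threshold, 0.05 / 3)
    expect_equal(nrow(scr$pairwise), 3L)
    expect_lt(scr$kruskal_p, 0.05)
    # Mann-Whitney p for a vs c against the exact U distribution
    pAC <- scr$pairwise$p[scr$pairwise$group1 == "a" &
                            scr$pairwise$group2 == "c"]
    expect_equal(pAC,
                 stats::wilcox.test(vals[groups == "a"], vals[groups == "c"],
                                    exact = TRUE)$p.value)
  })
})
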