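#' Cross-validation design configuration
#'
#' Grouped, repeated, shuffled k-fold cross-validation: `nShuffles`
#' independent re-randomizations of a `nFolds`-fold split of *patients*
#' (both lungs of a patient always share a fold), each fold's training
#' repeated `nRepeats` times. Defaults give the 10 x 5 x 5 design. Fold
#' assignment is stratified by label and depends only on `seed`, so every
#' masking scheme evaluated under one design sees identical splits.
#'
#' @param nShuffles,nFolds,nRepeats design counts.
#' @param seed integer seed for the fold randomizations.
#' @return list of class "CVDesign".
#' @export
cvDesign <- function(nShuffles = 10L, nFolds = 5L, nRepeats = 5L, seed = 1L) {
  structure(list(nShuffles = as.integer(nShuffles), nFolds = as.integer(nFolds),
                 nRepeats = as.integer(nRepeats), seed = as.integer(seed)),
            class = "CVDesign")
}

#' Assign patients to cross-validation folds
#'
#' For each shuffle, patients are partitioned into `nFolds` folds stratified
#' by label: within each class the patients are shuffled (seeded) and dealt
#' round-robin. Identical seed gives identical assignments, which is what
#' makes scheme comparisons paired.
#'
#' @param caseIds character vector of unique patient identifiers.
#' @param labels binary labels, one per patient.
#' @param cfg a [cvDesign()].
#' @return data.frame (shuffle, case_id, fold).
#' @export
buildCVDesign <- function(caseIds, labels, cfg = cvDesign()) {
  stopifnot(length(caseIds) == length(labels), !anyDuplicated(caseIds))
  if (length(caseIds) < cfg$nFolds)
    stop("fewer patients (", length(caseIds), ") than folds (", cfg$nFolds, ")")
  out <- vector("list", cfg$nShuffles)
  for (s in seq_len(cfg$nShuffles)) {
    fold <- integer(length(caseIds))
    withSeed(deriveSeed(cfg$seed, "shuffle", s), {
      for (cl in unique(labels)) {
        members <- which(labels == cl)
        members <- members[sample.int(length(members))]
        fold[members] <- rep_len(seq_len(cfg$nFolds), length(members))
      }
    })
    out[[s]] <- data.frame(shuffle = s, case_id = caseIds, fold = fold)
  }
  do.call(rbind, out)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability `P(score_pos > score_neg) +
#' 0.5 P(tie)` via midranks, which equals exhaustive pair counting with
#' half-credit ties.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run one masking-scheme experiment under grouped repeated CV
#'
#' For every shuffle, fold and repeat: a tail is trained (seeded
#' deterministically from the design seed and the shuffle/fold/repeat
#' indices) on the per-view features of both lungs of the training-fold
#' patients, and the hold-out patients are scored at the last epoch with the
#' lung-maximum of the two sigmoid(mean logit) lung scores. Fold-level
#' AUROCs are averaged over folds and repeats into one estimate per shuffle;
#' a hold-out fold lacking either class yields an undefined AUROC that is
#' flagged and excluded from the average with a warning. Patient-level
#' scores are the grand mean of each patient's hold-out lung-max scores over
#' repeats and shuffles.
#'
#' @param featureSet a feature table from [cohortFeatures()]: list with
#'   `cases` (data.frame case_id, label) and `feat[[case_id]]$left/right`
#'   (n_views x 1024 matrices).
#' @param cv a [cvDesign()].
#' @param train a [trainConfig()].
#' @param scheme,task labels recorded in the result.
#' @return An [ExperimentResult-class].
#' @export
runExperiment <- function(featureSet, cv = cvDesign(), train = trainConfig(),
                          scheme = "full", task = "task") {
  cases <- featureSet$cases
  design <- buildCVDesign(cases$case_id, cases$label, cv)
  nviews <- nrow(featureSet$feat[[cases$case_id[1]]]$left)

  shuffleAuroc <- numeric(cv$nShuffles)
  raw <- list()
  scoreSum <- setNames(numeric(nrow(cases)), cases$case_id)
  scoreN <- scoreSum
  for (s in seq_len(cv$nShuffles)) {
    d <- design[design$shuffle == s, ]
    foldAurocs <- c()
    for (f in seq_len(cv$nFolds)) {
      test <- d$case_id[d$fold == f]
      trainIds <- d$case_id[d$fold != f]
      ytr <- cases$label[match(trainIds, cases$case_id)]
      Xtr <- do.call(rbind, lapply(trainIds, function(id)
        rbind(featureSet$feat[[id]]$left, featureSet$feat[[id]]$right)))
      ytrRep <- rep(ytr, each = 2L * nviews)
      yte <- cases$label[match(test, cases$case_id)]
      for (r in seq_len(cv$nRepeats)) {
        cfg <- train
        cfg$seed <- deriveSeed(cv$seed, "train", s, f, r, scheme, task)
        fit <- trainTail(Xtr, ytrRep, cfg)
        lungMax <- vapply(test, function(id) {
          sl <- sigmoid(mean(tailLogits(fit$tail, featureSet$feat[[id]]$left)))
          sr <- sigmoid(mean(tailLogits(fit$tail, featureSet$feat[[id]]$right)))
          max(sl, sr)
        }, numeric(1))
        scoreSum[test] <- scoreSum[test] + lungMax
        scoreN[test] <- scoreN[test] + 1
        a <- if (length(unique(yte)) < 2L) {
          warning("hold-out fold ", f, " (shuffle ", s,
                  ") lacks a class; AUROC undefined, excluded")
          NA_real_
        } else auroc(lungMax, yte)
        foldAurocs <- c(foldAurocs, a)
        raw[[length(raw) + 1L]] <-
          data.frame(shuffle = s, fold = f, repeat_ = r, auroc = a)
      }
    }
    shuffleAuroc[s] <- mean(foldAurocs, na.rm = TRUE)
  }
  new("ExperimentResult", scheme = scheme, task = task,
      aurocPerShuffle = shuffleAuroc, rawAuroc = do.call(rbind, raw),
      patientScores = data.frame(case_id = cases$case_id,
                                 label = cases$label,
                                 score = as.numeric(scoreSum / scoreN)))
}

#' Compare masking schemes against a reference scheme
#'
#' All results must come from one shared CV design so the shuffle-level
#' AUROCs are paired. Runs Friedman's test for overall group differences
#' across the schemes, two-sided exact Wilcoxon signed-rank tests of every
#' scheme against the reference on the paired shuffle AUROCs with a
#' Bonferroni threshold of 0.05 divided by the number of comparisons, plus
#' Shapiro-Wilk normality and Levene variance-homogeneity screens.
#' A scheme compared with itself (all paired differences zero) gets an
#' undefined p-value and is never flagged significant.
#'
#' @param results named list of [ExperimentResult-class], one per scheme.
#' @param reference name of the reference scheme (default "full").
#' @return list: `table` (scheme, mean/min/max AUROC, p_vs_reference,
#'   significant), `friedman_p`, `shapiro_p` (per scheme), `levene_p`,
#'   `bonferroni_threshold`.
#' @export
compareSchemes <- function(results, reference = "full") {
  stopifnot(reference %in% names(results))
  mat <- vapply(results, aurocPerShuffle,
                numeric(length(aurocPerShuffle(results[[1]]))))
  if (any(is.na(mat))) stop("results contain undefined shuffle AUROCs")
  if (stats::var(c(vapply(results, function(r)
        length(aurocPerShuffle(r)), numeric(1)))) > 0)
    stop("results are unpaired: shuffle counts differ")
  nComp <- max(1L, ncol(mat) - 1L)
  thr <- 0.05 / nComp
  ref <- mat[, reference]
  rows <- lapply(colnames(mat), function(sc) {
    x <- mat[, sc]
    if (sc == reference) {
      p <- NA_real_
    } else if (all(x == ref)) {
      p <- NA_real_  # all paired differences zero: test undefined
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(x, ref, paired = TRUE, exact = TRUE)$p.value)
    }
    data.frame(scheme = sc, auroc_mean = mean(x), auroc_min = min(x),
               auroc_max = max(x), p_vs_reference = p,
               significant = !is.na(p) & p < thr)
  })
  long <- data.frame(auroc = as.numeric(mat),
                     scheme = factor(rep(colnames(mat), each = nrow(mat))))
  fr <- if (ncol(mat) >= 3L) stats::friedman.test(mat)$p.value else NA_real_
  shp <- vapply(colnames(mat), function(sc) {
    x <- mat[, sc]
    if (length(unique(x)) < 3L) NA_real_ else stats::shapiro.test(x)$p.value
  }, numeric(1))
  lev <- if (ncol(mat) >= 2L)
    car::leveneTest(auroc ~ scheme, data = long)[1, "Pr(>F)"] else NA_real_
  list(table = do.call(rbind, rows), friedman_p = fr, shapiro_p = shp,
       levene_p = lev, bonferroni_threshold = thr)
}

#' Ensemble classification decision per patient
#'
#' Per run: a patient votes positive when the larger of the two lung scores
#' exceeds the threshold (default 0.5). The final decision is the majority
#' over runs; an exact tie is resolved conservatively to negative and
#' flagged.
#'
#' @param runScores data.frame with columns case_id, run, left, right (lung
#'   scores per training run).
#' @param threshold decision threshold on the lung-maximum score.
#' @return data.frame (case_id, decision, pos_votes, n_runs, tie).
#' @export
ensembleDecision <- function(runScores, threshold = 0.5) {
  need <- c("case_id", "run", "left", "right")
  stopifnot(all(need %in% names(runScores)))
  if (anyNA(runScores$left) || anyNA(runScores$right))
    stop("missing lung score")
  votes <- pmax(runScores$left, runScores$right) > threshold
  agg <- aggregate(votes, by = list(case_id = runScores$case_id),
                   FUN = function(v) c(sum(v), length(v)))
  pos <- agg$x[, 1]; n <- agg$x[, 2]
  tie <- pos * 2 == n
  if (any(tie)) warning("majority-vote tie for ", sum(tie),
                        " case(s); resolved to negative")
  data.frame(case_id = agg$case_id,
             decision = as.integer(pos * 2 > n),
             pos_votes = pos, n_runs = n, tie = tie)
}

#' Reference vessel-size measurements
#'
#' Two scalar measurements used as non-deep-learning baselines: the volume
#' of the proximal-vessel addition mask (mL), and the cross-sectional area
#' (cm^2) of the vessel at a given point (which must lie inside the addition
#' mask), measured in the plane through `paPoint` perpendicular to `paAxis`,
#' restricted to above-threshold voxels inside the full segmentation and
#' connected in-plane to the point — so the measured vessel may continue
#' from the proximal addition into the segmented lung, while unsegmented
#' mediastinal structures never contribute.
#'
#' @param vol a [CTVolume-class].
#' @param masks a [LungMaskSet-class]; both sides' addition masks are pooled.
#' @param paPoint numeric(3) point in mm inside the addition mask.
#' @param paAxis numeric(3) vessel axis direction (normalized internally).
#' @param vesselThresholdHU HU threshold separating contrast-filled vessel
#'   from background (default 0).
#' @param planeStepMM in-plane sampling pitch in mm (default half the
#'   smallest voxel spacing).
#' @return list of class "MeasurementRecord": `added_volume_ml`,
#'   `pa_cross_section_cm2`.
#' @export
measureReference <- function(vol, masks, paPoint, paAxis,
                             vesselThresholdHU = 0, planeStepMM = NULL) {
  stopifnot(is(vol, "CTVolume"), is(masks, "LungMaskSet"))
  sp <- vol@spacing
  gs <- dim(vol@data)
  addition <- maskArray(masks, "left", "addition") |
    maskArray(masks, "right", "addition")
  segmented <- addition | maskArray(masks, "left", "initial") |
    maskArray(masks, "right", "initial")
  vox <- pmin(pmax(ceiling(paPoint / sp), 1L), gs)
  if (!addition[vox[1], vox[2], vox[3]])
    stop("paPoint is not inside the addition mask")
  addedML <- sum(addition) * voxelVolumeML(sp)

  ax <- paAxis / sqrt(sum(paAxis^2))
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- pracmaCross(ax, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracmaCross(ax, e1)
  if (is.null(planeStepMM)) planeStepMM <- min(sp) / 2
  halfExtent <- max(gs * sp) / 2
  uu <- seq(-halfExtent, halfExtent, by = planeStepMM)
  ngrid <- length(uu)
  inVessel <- matrix(FALSE, ngrid, ngrid)
  for (j in seq_len(ngrid)) {
    pts <- cbind(paPoint[1] + uu * e1[1] + uu[j] * e2[1],
                 paPoint[2] + uu * e1[2] + uu[j] * e2[2],
                 paPoint[3] + uu * e1[3] + uu[j] * e2[3])
    iv <- ceiling(sweep(pts, 2, sp, "/"))
    ok <- iv[, 1] >= 1 & iv[, 1] <= gs[1] & iv[, 2] >= 1 & iv[, 2] <= gs[2] &
      iv[, 3] >= 1 & iv[, 3] <= gs[3]
    lin <- iv[ok, 1] + gs[1] * (iv[ok, 2] - 1) + gs[1] * gs[2] * (iv[ok, 3] - 1)
    inVessel[ok, j] <- segmented[lin] & vol@data[lin] > vesselThresholdHU
  }
  # in-plane connected component (4-connectivity) containing the point
  c0 <- which.min(abs(uu))
  comp <- matrix(FALSE, ngrid, ngrid)
  if (inVessel[c0, c0]) {
    queue <- matrix(c(c0, c0), ncol = 2)
    comp[c0, c0] <- TRUE
    while (nrow(queue) > 0) {
      cur <- queue[nrow(queue), , drop = FALSE]
      queue <- queue[-nrow(queue), , drop = FALSE]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
        if (ni >= 1 && ni <= ngrid && nj >= 1 && nj <= ngrid &&
            inVessel[ni, nj] && !comp[ni, nj]) {
          comp[ni, nj] <- TRUE
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  areaCM2 <- sum(comp) * planeStepMM^2 / 100
  structure(list(added_volume_ml = addedML, pa_cross_section_cm2 = areaCM2),
            class = "MeasurementRecord")
}

#' Scalar-measurement AUROC with bootstrap confidence interval
#'
#' AUROC of a scalar measurement separating two groups, with a seeded
#' stratified percentile bootstrap (resampling within each group).
#'
#' @param valuesPos,valuesNeg measurement values for the two groups.
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return list: `auroc`, `ci` (length 2), `n_boot`.
#' @export
scalarAurocCI <- function(valuesPos, valuesNeg, nBoot = 2000L, seed = 1L,
                          conf = 0.95) {
  stopifnot(length(valuesPos) > 0, length(valuesNeg) > 0)
  scores <- c(valuesPos, valuesNeg)
  labels <- rep(c(1L, 0L), c(length(valuesPos), length(valuesNeg)))
  est <- auroc(scores, labels)
  boot <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    p <- sample(valuesPos, replace = TRUE)
    n <- sample(valuesNeg, replace = TRUE)
    auroc(c(p, n), rep(c(1L, 0L), c(length(p), length(n))))
  }, numeric(1)))
  a <- (1 - conf) / 2
  list(auroc = est,
       ci = unname(stats::quantile(boot, c(a, 1 - a), type = 7)),
       n_boot = nBoot)
}

#' Rank-based group screens for scalar measurements
#'
#' Thin contract over the standard rank tests used for scalar vessel
#' measurements: a Kruskal-Wallis test for any group-level difference,
#' followed by pairwise two-sided Mann-Whitney U tests with a Bonferroni
#' threshold of 0.05 divided by the number of pairs.
#'
#' @param values numeric measurements.
#' @param groups group labels (factor or character).
#' @return list: `kruskal_p`, `pairwise` (data.frame group1, group2, p,
#'   significant), `bonferroni_threshold`.
#' @export
groupRankTests <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) >= 2L)
  kw <- stats::kruskal.test(values, groups)$p.value
  prs <- utils::combn(levels(groups), 2)
  thr <- 0.05 / ncol(prs)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    g1 <- prs[1, k]; g2 <- prs[2, k]
    p <- suppressWarnings(stats::wilcox.test(values[groups == g1],
                                             values[groups == g2])$p.value)
    data.frame(group1 = g1, group2 = g2, p = p, significant = p < thr)
  })
  list(kruskal_p = kw, pairwise = do.call(rbind, rows),
       bonferroni_threshold = thr)
}
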