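# Independent oracles used to pin down expected values.

# Brute-force central-to-peripheral ordering: sort in-mask voxels by
# descending HU; every voxel's fraction is the cumulative count of voxels
# with HU >= its own, divided by the mask size (ties share one value).
# Matches the threshold descent with closing disabled on integer-HU volumes
# (each 1-HU descent step then holds exactly one distinct value).
oracleFractionMap <- function(hu, mask) {
  frac <- array(NA_real_, dim(hu))
  vals <- hu[mask]
  n <- length(vals)
  cum_ge <- vapply(vals, function(v) sum(vals >= v), numeric(1))
  frac[mask] <- cum_ge / n
  frac
}

# Exhaustive pair-counting AUROC with half-credit ties.
oracleAuroc <- function(scores, labels) {
  p <- scores[labels == 1]
  n <- scores[labels == 0]
  tot <- 0
  for (a in p) for (b in n) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(n))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
# (no ties, no zeros assumed).
oracleSignedRankP <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dist <- as.numeric(signs %*% r)
  mean(dist <= min(w, sum(r) - w)) + mean(dist >= max(w, sum(r) - w))
}

# A tail whose forward pass copies feature column 1 to the logit
# (batch-norm layers tuned to exact identity: with eps = 1e-5, running
# variance 1 - 1e-5 makes the normalizer exactly 1).
passthroughTail <- function(featureLen = 8L) {
  cfg <- tailConfig(featureLen = featureLen, fc1 = 4L, fc2 = 4L)
  tail <- initTail(cfg, seed = 1L)
  idbn <- function(k) list(g = rep(1, k), b = rep(0, k), rm = rep(0, k),
                           rv = rep(1 - 1e-5, k))
  tail$bn1 <- idbn(featureLen)
  tail$bn2 <- idbn(4L)
  tail$bn3 <- idbn(4L)
  tail$W1 <- matrix(0, featureLen, 4L); tail$W1[1, 1] <- 1
  tail$b1 <- rep(0, 4L)
  tail$W2 <- matrix(0, 4L, 4L); tail$W2[1, 1] <- 1
  tail$b2 <- rep(0, 4L)
  tail$W3 <- matrix(0, 4L, 1L); tail$W3[1, 1] <- 1
  tail$b3 <- 0
  tail
}

# Encoder stub whose "features" are fixed per-view values in column 1.
constantEncoder <- function(columnValues, featureLen = 8L) {
  list(name = "fixture", featureLen = featureLen,
       fn = function(images) {
         n <- dim(images)[3]
         stopifnot(n == length(columnValues))
         m <- matrix(0, n, featureLen)
         m[, 1] <- columnValues
         m
       })
}

# Small MIPSet with arbitrary content for classifier fixtures.
dummyMIPSet <- function(nViews = 11L, size = 16L) {
  views <- do.call(rbind, lapply(seq_len(nViews), function(k)
    data.frame(axis = "vertical", angle_deg = k, is_baseline = FALSE,
               inplane_deg = 0)))
  new("MIPSet", images = array(0.5, c(size, size, nViews)), views = views,
      scheme = "full", side = "left", window = c(200, 700))
}

# Random integer-HU test grid with a random mask.
randomGrid <- function(shape = c(8, 8, 8), pMask = 0.5, huRange = c(0, 60)) {
  hu <- array(sample(huRange[1]:huRange[2], prod(shape), replace = TRUE),
              shape)
  mask <- array(stats::runif(prod(shape)) < pMask, shape)
  if (!any(mask)) mask[1] <- TRUE
  list(vol = CTVolume(hu, c(1, 1, 1)), mask = mask)
}

# frozen projection-encoder outputs for the two-step test image
# (computed once from getEncoder("projection"), columns 1, 2, 515, 1024)
REGRESSION_FEATURES <- c(-0.638375867540, 0.340973566348,
                         0.976194157437, -0.678531427080)
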