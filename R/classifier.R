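#' Encoder registry
#'
#' The classifier separates a *frozen* image encoder from a trainable tail.
#' Encoders are pluggable behind a fixed contract: given a stack of 224 x 224
#' grayscale images in \[0, 1\], produce one 1024-element feature vector per
#' image, deterministically (frozen weights). The built-in `"projection"`
#' encoder average-pools each image to 16 x 16 and applies a fixed seeded
#' random projection to 1024 features with a tanh squashing — a deterministic,
#' dependency-free encoder whose features preserve linear separability of the
#' pooled images. Additional encoders (e.g. pretrained CNN backbones) can be
#' registered by passing a compatible function to [encodeMIPSet()].
#'
#' @param name encoder identifier; `"projection"` is built in.
#' @return list with `name`, `featureLen` and `fn(images)` mapping an
#'   (h, w, n) array to an n x featureLen matrix.
#' @export
getEncoder <- function(name = "projection") {
  if (is.list(name) && !is.null(name$fn)) return(name)
  if (!identical(name, "projection"))
    stop("unknown encoder: ", name)
  featureLen <- 1024L
  poolTo <- 16L
  W <- withSeed(913721L, matrix(stats::rnorm(poolTo^2 * featureLen,
                                             sd = 1 / poolTo),
                                nrow = poolTo^2))
  fn <- function(images) {
    d <- dim(images)
    if (length(d) == 2L) { images <- array(images, c(d, 1L)); d <- dim(images) }
    if (d[1] != 224L || d[2] != 224L)
      stop("encoder expects 224x224 images, got ", d[1], "x", d[2])
    block <- 224L / poolTo
    feats <- matrix(0, d[3], featureLen)
    for (k in seq_len(d[3])) {
      img <- images[, , k]
      pooled <- .colMeans(matrix(aperm(array(img, c(block, poolTo, block, poolTo)),
                                       c(1, 3, 2, 4)),
                                 nrow = block * block),
                          block * block, poolTo * poolTo)
      feats[k, ] <- tanh(4 * pooled %*% W)
    }
    feats
  }
  list(name = "projection", featureLen = featureLen, fn = fn)
}

#' Encode a MIPSet into per-view feature vectors
#'
#' @param mipSet a [MIPSet-class] (or bare image array).
#' @param encoder an encoder identifier or list from [getEncoder()].
#' @return n_views x 1024 feature matrix.
#' @export
encodeMIPSet <- function(mipSet, encoder = "projection") {
  enc <- getEncoder(encoder)
  imgs <- if (is(mipSet, "MIPSet")) mipSet@images else mipSet
  enc$fn(imgs)
}

#' Tail architecture configuration
#'
#' The trainable classification tail applied to each per-view feature vector:
#' batch normalization, a 1024-unit fully connected layer, Alpha Dropout
#' (p = 0.3), batch normalization, a 512-unit fully connected layer, Alpha
#' Dropout (0.3), batch normalization, and a final 1-logit fully connected
#' layer.
#'
#' @param featureLen encoder feature length (1024).
#' @param fc1,fc2 hidden-layer widths.
#' @param dropoutP Alpha-Dropout drop probability.
#' @return list of class "TailConfig".
#' @export
tailConfig <- function(featureLen = 1024L, fc1 = 1024L, fc2 = 512L,
                       dropoutP = 0.3) {
  structure(list(featureLen = as.integer(featureLen), fc1 = as.integer(fc1),
                 fc2 = as.integer(fc2), dropoutP = dropoutP),
            class = "TailConfig")
}

#' Training configuration
#'
#' Defaults reproduce the fixed training protocol used throughout: 30 epochs,
#' batch size 8, Adam (learning rate 2e-4, weight decay 1e-3), cosine
#' learning-rate decay, binary cross-entropy on logits. No hyperparameter
#' tuning is performed anywhere in the package.
#'
#' @param epochs,batchSize,lr,weightDecay,seed see description.
#' @param tail a [tailConfig()].
#' @param encoder encoder identifier.
#' @return list of class "TrainConfig".
#' @export
trainConfig <- function(epochs = 30L, batchSize = 8L, lr = 2e-4,
                        weightDecay = 1e-3, seed = 1L, tail = tailConfig(),
                        encoder = "projection") {
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 lr = lr, weightDecay = weightDecay, seed = as.integer(seed),
                 tail = tail, encoder = encoder),
            class = "TrainConfig")
}

#' Cosine learning-rate schedule
#'
#' `lr0 * (1 + cos(pi * epoch / total)) / 2` with `epoch` counted from 0, so
#' the first epoch trains at `lr0` and the rate anneals towards 0.
#'
#' @param epoch 0-based epoch index.
#' @param total total number of epochs.
#' @param lr0 initial learning rate.
#' @return learning rate for that epoch.
#' @export
cosineLR <- function(epoch, total, lr0) lr0 * (1 + cos(pi * epoch / total)) / 2

## ---- tail internals: initialization, forward, backward, Adam ----

initTail <- function(cfg = tailConfig(), seed = 1L) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  withSeed(seed, {
    list(cfg = cfg,
         bn1 = list(g = rep(1, cfg$featureLen), b = rep(0, cfg$featureLen),
                    rm = rep(0, cfg$featureLen), rv = rep(1, cfg$featureLen)),
         W1 = he(cfg$featureLen, cfg$fc1), b1 = rep(0, cfg$fc1),
         bn2 = list(g = rep(1, cfg$fc1), b = rep(0, cfg$fc1),
                    rm = rep(0, cfg$fc1), rv = rep(1, cfg$fc1)),
         W2 = he(cfg$fc1, cfg$fc2), b2 = rep(0, cfg$fc2),
         bn3 = list(g = rep(1, cfg$fc2), b = rep(0, cfg$fc2),
                    rm = rep(0, cfg$fc2), rv = rep(1, cfg$fc2)),
         W3 = he(cfg$fc2, 1L), b3 = 0)
  })
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bnForward <- function(x, bn, training) {
  if (training && nrow(x) > 1L) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    va <- colMeans(xc^2)
    xhat <- sweep(xc, 2, sqrt(va + BN_EPS), "/")
    bn$rm <- (1 - BN_MOMENTUM) * bn$rm + BN_MOMENTUM * mu
    bn$rv <- (1 - BN_MOMENTUM) * bn$rv + BN_MOMENTUM * va
    list(y = sweep(sweep(xhat, 2, bn$g, "*"), 2, bn$b, "+"),
         xhat = xhat, va = va, bn = bn)
  } else {
    xhat <- sweep(sweep(x, 2, bn$rm), 2, sqrt(bn$rv + BN_EPS), "/")
    list(y = sweep(sweep(xhat, 2, bn$g, "*"), 2, bn$b, "+"),
         xhat = xhat, va = bn$rv, bn = bn)
  }
}

bnBackward <- function(dy, cache, g) {
  n <- nrow(dy)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, "*")
  dx <- sweep(dxhat -
                matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
                cache$xhat * matrix(colMeans(dxhat * cache$xhat), n, ncol(dy),
                                    byrow = TRUE),
              2, sqrt(cache$va + BN_EPS), "/")
  list(dx = dx, dg = dg, db = db)
}

# Alpha Dropout (SELU family): drops to the SELU negative saturation value
# and rescales affinely so mean and variance are preserved in expectation.
AD_ALPHA_P <- -1.7580993408473766
adForward <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL, a = 1, p = p))
  q <- 1 - p
  a <- (q + AD_ALPHA_P^2 * q * p)^-0.5
  b <- -a * p * AD_ALPHA_P
  mask <- matrix(stats::runif(length(x)) < q, nrow(x), ncol(x))
  list(y = a * (x * mask + AD_ALPHA_P * (1 - mask)) + b, mask = mask, a = a,
       p = p)
}

adBackward <- function(dy, cache) {
  if (is.null(cache$mask)) return(dy)
  dy * cache$a * cache$mask
}

tailForward <- function(tail, x, training = FALSE) {
  c1 <- bnForward(x, tail$bn1, training); tail$bn1 <- c1$bn
  z1 <- sweep(c1$y %*% tail$W1, 2, tail$b1, "+")
  d1 <- adForward(z1, tail$cfg$dropoutP, training)
  c2 <- bnForward(d1$y, tail$bn2, training); tail$bn2 <- c2$bn
  z2 <- sweep(c2$y %*% tail$W2, 2, tail$b2, "+")
  d2 <- adForward(z2, tail$cfg$dropoutP, training)
  c3 <- bnForward(d2$y, tail$bn3, training); tail$bn3 <- c3$bn
  logits <- as.numeric(c3$y %*% tail$W3 + tail$b3)
  list(logits = logits, tail = tail,
       cache = list(c1 = c1, d1 = d1, c2 = c2, d2 = d2, c3 = c3, x = x))
}

tailBackward <- function(tail, cache, dlogits) {
  n <- length(dlogits)
  dy3 <- matrix(dlogits, n, 1)
  dW3 <- crossprod(cache$c3$y, dy3)
  db3 <- sum(dy3)
  dc3 <- tcrossprod(dy3, tail$W3)
  b3 <- bnBackward(dc3, cache$c3, tail$bn3$g)
  dz2 <- adBackward(b3$dx, cache$d2)
  dW2 <- crossprod(cache$c2$y, dz2)
  db2 <- colSums(dz2)
  dc2 <- tcrossprod(dz2, tail$W2)
  b2 <- bnBackward(dc2, cache$c2, tail$bn2$g)
  dz1 <- adBackward(b2$dx, cache$d1)
  dW1 <- crossprod(cache$c1$y, dz1)
  db1 <- colSums(dz1)
  dc1 <- tcrossprod(dz1, tail$W1)
  b1 <- bnBackward(dc1, cache$c1, tail$bn1$g)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3,
       bn1g = b1$dg, bn1b = b1$db, bn2g = b2$dg, bn2b = b2$db,
       bn3g = b3$dg, bn3b = b3$db)
}

bceWithLogits <- function(logits, y) {
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

# Adam state lives in plain vectors updated in place by the C++ kernel; the
# wrapper guarantees the weights are un-shared copies first.
adamStateFor <- function(w) list(m = w * 0, v = w * 0)

#' Train the classification tail on encoded features
#'
#' Each 1024-element feature vector (one per MIP view; left and right lungs
#' enter as separate samples carrying the case's label) is a training sample.
#' Optimization is Adam with coupled L2 weight decay, cosine learning-rate
#' decay across the epochs, and binary cross-entropy on the logit. All
#' randomness (weight init, shuffling, dropout) flows from `cfg$seed`, so a
#' fixed seed gives an identical loss trace.
#'
#' @param features numeric matrix, samples x featureLen.
#' @param labels binary vector (one per sample).
#' @param cfg a [trainConfig()].
#' @return list: `tail` (trained weights, evaluation-ready), `loss` (mean
#'   training loss per epoch), `lr` (learning rate per epoch).
#' @export
trainTail <- function(features, labels, cfg = trainConfig()) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class; need both labels")
  tail <- initTail(cfg$tail, seed = deriveSeed(cfg$seed, "init"))
  decayed <- c("W1", "W2", "W3")  # weight decay on connection weights
  params <- c("W1", "b1", "W2", "b2", "W3", "b3",
              "bn1g", "bn1b", "bn2g", "bn2b", "bn3g", "bn3b")
  getp <- function(nm) switch(nm,
    bn1g = tail$bn1$g, bn1b = tail$bn1$b, bn2g = tail$bn2$g,
    bn2b = tail$bn2$b, bn3g = tail$bn3$g, bn3b = tail$bn3$b, tail[[nm]])
  setp <- function(nm, w) {
    if (startsWith(nm, "bn")) {
      sl <- substr(nm, 1, 3); fld <- substr(nm, 4, 4)
      tail[[sl]][[if (fld == "g") "g" else "b"]] <<- w
    } else tail[[nm]] <<- w
  }
  # force un-shared copies so the in-place Adam kernel cannot alias anything
  for (nm in params) setp(nm, getp(nm) + 0)
  opt <- lapply(params, function(nm) adamStateFor(getp(nm)))
  names(opt) <- params
  t <- 0L
  n <- nrow(features)
  lossTrace <- numeric(cfg$epochs)
  lrTrace <- numeric(cfg$epochs)
  withSeed(deriveSeed(cfg$seed, "epochs"), {
    for (e in seq_len(cfg$epochs)) {
      lr <- cosineLR(e - 1L, cfg$epochs, cfg$lr)
      lrTrace[e] <- lr
      ord <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = cfg$batchSize)) {
        idx <- ord[b0:min(b0 + cfg$batchSize - 1L, n)]
        if (length(idx) < 2L) next  # batch statistics need >= 2 samples
        fw <- tailForward(tail, features[idx, , drop = FALSE], training = TRUE)
        tail <- fw$tail
        y <- labels[idx]
        losses <- c(losses, bceWithLogits(fw$logits, y))
        dlogits <- (sigmoid(fw$logits) - y) / length(idx)
        gr <- tailBackward(tail, fw$cache, dlogits)
        t <- t + 1L
        for (nm in params) {
          wd <- if (nm %in% decayed) cfg$weightDecay else 0
          cpp_adam_step(getp(nm), gr[[nm]], opt[[nm]]$m, opt[[nm]]$v,
                        lr, t, wd, 0.9, 0.999, 1e-8)
        }
      }
      lossTrace[e] <- mean(losses)
    }
  })
  list(tail = tail, loss = lossTrace, lr = lrTrace)
}

#' Logits for encoded features under a trained tail (evaluation mode)
#'
#' Dropout is off and batch normalization uses running statistics, so the
#' output is a pure function of (weights, inputs).
#'
#' @param tail trained tail weights (from [trainTail()]`$tail`).
#' @param features samples x featureLen matrix.
#' @return numeric vector of logits.
#' @export
tailLogits <- function(tail, features) {
  tailForward(tail, features, training = FALSE)$logits
}

#' Predict one lung from its MIPSet
#'
#' Every view is encoded and passed through the tail; the eleven per-view
#' logits are averaged and squashed, so the lung score is
#' `sigmoid(mean(logits))` — averaging happens on the logit scale, before the
#' sigmoid.
#'
#' @param mipSet a [MIPSet-class] with exactly 11 views.
#' @param tail trained tail weights.
#' @param encoder encoder identifier or [getEncoder()] list.
#' @return list of class "LungPrediction": `side`, `score` (in (0,1)),
#'   `perViewLogits`, `perViewScores`.
#' @export
predictLung <- function(mipSet, tail, encoder = "projection") {
  stopifnot(is(mipSet, "MIPSet"))
  if (dim(mipSet@images)[3] != 11L)
    stop("predictLung expects exactly 11 views, got ", dim(mipSet@images)[3])
  feats <- encodeMIPSet(mipSet, encoder)
  logits <- tailLogits(tail, feats)
  structure(list(side = mipSet@side, score = sigmoid(mean(logits)),
                 perViewLogits = logits, perViewScores = sigmoid(logits)),
            class = "LungPrediction")
}

#' Save or load trained tail weights
#'
#' Weights go to an RDS array archive with a human-readable JSON sidecar
#' describing the architecture and training configuration, so a saved tail
#' can be audited without loading it.
#'
#' @param fit a [trainTail()] result (or a bare tail weight list).
#' @param path base path; `<path>.rds` and `<path>.json` are written.
#' @return `saveTail` returns `path` invisibly; `loadTail` returns the tail
#'   weight list ready for [tailLogits()] / [predictLung()].
#' @export
saveTail <- function(fit, path) {
  tail <- if (!is.null(fit$tail)) fit$tail else fit
  saveRDS(tail, paste0(path, ".rds"))
  jsonlite::write_json(
    list(featureLen = tail$cfg$featureLen, fc1 = tail$cfg$fc1,
         fc2 = tail$cfg$fc2, dropoutP = tail$cfg$dropoutP,
         loss = fit$loss, lr = fit$lr),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveTail
#' @export
loadTail <- function(path) readRDS(paste0(path, ".rds"))
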