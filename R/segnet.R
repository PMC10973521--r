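## Encoder-decoder semantic segmentation with max-pooling-index unpooling,
## implemented directly on BLAS matrix products (3x3 convolutions as nine
## shifted GEMMs). The "full" scale mirrors the first 13 convolutional layers
## of VGG16 in the encoder and 13 in the decoder; the "desk" scale keeps the
## same topology (conv + ReLU + 2x2 pool with remembered argmax indices,
## mirrored by unpool + conv) reduced to 4 single-convolution blocks of at
## most 32 channels, small enough to train on one CPU. Training is plain SGD
## with momentum on the per-pixel cross-entropy, selecting the parameters
## with the best validation loss.

## ---- layer primitives -----------------------------------------------------

.convForward <- function(x, Wt, b) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; Cin <- d[3L]; Cout <- dim(Wt)[4L]
  xp <- array(0, c(H + 2L, W + 2L, Cin))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  out <- matrix(b, H * W, Cout, byrow = TRUE)
  for (di in 0:2) for (dj in 0:2) {
    M <- matrix(xp[di + seq_len(H), dj + seq_len(W), ], H * W, Cin)
    out <- out + M %*% matrix(Wt[di + 1L, dj + 1L, , ], Cin, Cout)
  }
  list(y = array(out, c(H, W, Cout)), xp = xp)
}

.convBackward <- function(dy, xp, Wt) {
  d <- dim(dy); H <- d[1L]; W <- d[2L]; Cout <- d[3L]; Cin <- dim(Wt)[3L]
  dyM <- matrix(dy, H * W, Cout)
  dW <- array(0, dim(Wt))
  dxp <- array(0, dim(xp))
  for (di in 0:2) for (dj in 0:2) {
    M <- matrix(xp[di + seq_len(H), dj + seq_len(W), ], H * W, Cin)
    dW[di + 1L, dj + 1L, , ] <- crossprod(M, dyM)
    dxp[di + seq_len(H), dj + seq_len(W), ] <-
      dxp[di + seq_len(H), dj + seq_len(W), , drop = FALSE] +
      array(tcrossprod(dyM, matrix(Wt[di + 1L, dj + 1L, , ], Cin, Cout)), c(H, W, Cin))
  }
  list(dx = dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE], dW = dW, db = colSums(dyM))
}

## 2x2 max pooling; odd inputs are padded with -Inf. Returns the linear
## indices of the argmax positions in the (padded) input so the matching
## decoder unpool can scatter into exactly those positions.
.poolForward <- function(x) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]
  H2 <- 2L * ((H + 1L) %/% 2L); W2 <- 2L * ((W + 1L) %/% 2L)
  if (H2 != H || W2 != W) {
    xp <- array(-Inf, c(H2, W2, C)); xp[seq_len(H), seq_len(W), ] <- x
  } else xp <- x
  hp <- H2 %/% 2L; wp <- W2 %/% 2L
  r1 <- seq(1L, H2, 2L); c1 <- seq(1L, W2, 2L)
  m4 <- cbind(as.vector(xp[r1, c1, ]), as.vector(xp[r1, c1 + 1L, ]),
              as.vector(xp[r1 + 1L, c1, ]), as.vector(xp[r1 + 1L, c1 + 1L, ]))
  k <- max.col(m4, ties.method = "first")
  n <- length(k)
  e <- seq_len(n) - 1L
  i <- e %% hp; j <- (e %/% hp) %% wp; ch <- e %/% (hp * wp)
  row <- 2L * i + 1L + (k > 2L)
  col <- 2L * j + 1L + (k %% 2L == 0L)
  lin <- row + (col - 1L) * H2 + ch * (H2 * W2)
  list(y = array(m4[cbind(seq_len(n), k)], c(hp, wp, C)),
       lin = lin, inDim = c(H, W, C), padDim = c(H2, W2, C))
}

.poolBackward <- function(dy, cache) {
  g <- array(0, cache$padDim)
  g[cache$lin] <- dy
  g[seq_len(cache$inDim[1L]), seq_len(cache$inDim[2L]), , drop = FALSE]
}

.unpoolForward <- function(x, cache) {
  g <- array(0, cache$padDim)
  g[cache$lin] <- x
  g[seq_len(cache$inDim[1L]), seq_len(cache$inDim[2L]), , drop = FALSE]
}

.unpoolBackward <- function(dy, cache) {
  g <- array(0, cache$padDim)
  g[seq_len(cache$inDim[1L]), seq_len(cache$inDim[2L]), ] <- dy
  array(g[cache$lin], c(cache$padDim[1L] %/% 2L, cache$padDim[2L] %/% 2L, cache$padDim[3L]))
}

## Per-channel feature normalisation (the batch-normalisation role in the
## original encoder-decoder design; computed over the pixels of the image
## being processed, so it is deterministic and identical in training and
## inference). y = gamma * (x - mu) / sqrt(var + eps) + beta.
.bnForward <- function(x, g, be, eps = 1e-5) {
  d <- dim(x); N <- prod(d[1:2])
  xm <- matrix(x, N, d[3L])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  s <- sqrt(colSums(xc^2) / N + eps)
  xhat <- sweep(xc, 2L, s, "/")
  y <- sweep(sweep(xhat, 2L, g, "*"), 2L, be, "+")
  list(y = array(y, d), xhat = xhat, s = s)
}

.bnBackward <- function(dy, cache, g) {
  d <- dim(dy); N <- prod(d[1:2])
  dym <- matrix(dy, N, d[3L])
  dg <- colSums(dym * cache$xhat)
  dbe <- colSums(dym)
  dxhat <- sweep(dym, 2L, g, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(sweep(dxhat, 2L, m1) - sweep(cache$xhat, 2L, m2, "*"), 2L, cache$s, "/")
  list(dx = array(dx, d), dg = dg, dbe = dbe)
}

.softmaxProbs <- function(logits) {
  d <- dim(logits); K <- d[3L]
  m <- matrix(logits, prod(d[1:2]), K)
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  array(e / rowSums(e), d)
}

## ---- architecture ---------------------------------------------------------

.segArchitecture <- function(scale, classes, inChannels) {
  if (scale == "full") {
    list(blocks = list(c(64, 64), c(128, 128), c(256, 256, 256),
                       c(512, 512, 512), c(512, 512, 512)),
         inChannels = if (is.null(inChannels)) 3L else inChannels,
         classes = classes)
  } else {
    list(blocks = list(8, 16, 24, 32),
         inChannels = if (is.null(inChannels)) 1L else inChannels,
         classes = classes)
  }
}

## Channel plan: encoder conv l of block b maps prev -> blocks[[b]][l].
## Decoder mirrors the encoder deepest-first; the final decoder convolution
## maps to the class count and feeds the softmax.
.initSegParams <- function(cfg, seed) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  mkConv <- function(cin, cout, bn = TRUE) {
    p <- list(W = array(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
                        c(3L, 3L, cin, cout)),
              b = numeric(cout))
    if (bn) { p$g <- rep(1, cout); p$be <- numeric(cout) }
    p
  }
  enc <- list(); prev <- cfg$inChannels
  for (b in seq_along(cfg$blocks)) {
    blk <- list()
    for (cout in cfg$blocks[[b]]) { blk[[length(blk) + 1L]] <- mkConv(prev, cout); prev <- cout }
    enc[[b]] <- blk
  }
  dec <- list()
  nb <- length(cfg$blocks)
  for (b in nb:1) {
    cb <- cfg$blocks[[b]]
    tgt <- if (b > 1L) rev(c(cfg$blocks[[b - 1L]][length(cfg$blocks[[b - 1L]])], cb[-length(cb)]))
           else rev(c(cfg$classes, cb[-length(cb)]))
    blk <- list(); prev <- cb[length(cb)]
    for (li in seq_along(tgt)) {
      isLogits <- (b == 1L) && (li == length(tgt))
      blk[[length(blk) + 1L]] <- mkConv(prev, tgt[li], bn = !isLogits)
      prev <- tgt[li]
    }
    dec[[nb - b + 1L]] <- blk
  }
  list(encoder = enc, decoder = dec)
}

#' Build an encoder-decoder segmentation model
#'
#' @param scale `"desk"` (4 blocks, <= 32 channels, CPU-trainable) or
#'   `"full"` (VGG16-width 13 + 13 convolutional layers).
#' @param classes number of output classes including background.
#' @param inChannels input channels (defaults: 1 for desk, 3 for full;
#'   grayscale inputs are replicated to the expected channel count).
#' @param seed deterministic initialisation seed.
#' @return An untrained [SegModel-class].
#' @export
buildSegModel <- function(scale = c("desk", "full"), classes = 2L,
                          inChannels = NULL, seed = 1) {
  scale <- match.arg(scale)
  cfg <- .segArchitecture(scale, as.integer(classes), inChannels)
  new("SegModel", scale = scale, config = cfg,
      params = .initSegParams(cfg, seed), classes = as.integer(classes),
      trained = FALSE, seed = seed,
      history = data.frame(epoch = integer(0), train_loss = numeric(0),
                           val_loss = numeric(0)))
}

## ---- forward / backward engine --------------------------------------------

.segForward <- function(params, x, labels = NULL, wantGrad = FALSE,
                        classWeights = NULL) {
  encCaches <- list(); poolCaches <- list()
  nb <- length(params$encoder)
  for (b in seq_len(nb)) {
    blkCache <- list()
    for (l in seq_along(params$encoder[[b]])) {
      cp <- params$encoder[[b]][[l]]
      cf <- .convForward(x, cp$W, cp$b)
      bnc <- .bnForward(cf$y, cp$g, cp$be)
      x <- pmax(bnc$y, 0)
      blkCache[[l]] <- list(xp = cf$xp, bn = bnc[c("xhat", "s")], act = bnc$y > 0)
    }
    pc <- .poolForward(x)
    x <- pc$y
    encCaches[[b]] <- blkCache
    poolCaches[[b]] <- pc[c("lin", "inDim", "padDim")]
  }
  decCaches <- list()
  for (i in seq_len(nb)) {          # deepest encoder block first
    b <- nb - i + 1L
    x <- .unpoolForward(x, poolCaches[[b]])
    blkCache <- list()
    for (l in seq_along(params$decoder[[i]])) {
      cp <- params$decoder[[i]][[l]]
      cf <- .convForward(x, cp$W, cp$b)
      last <- (i == nb) && (l == length(params$decoder[[i]]))
      if (last) {
        x <- cf$y
        blkCache[[l]] <- list(xp = cf$xp, bn = NULL, act = NULL)
      } else {
        bnc <- .bnForward(cf$y, cp$g, cp$be)
        x <- pmax(bnc$y, 0)
        blkCache[[l]] <- list(xp = cf$xp, bn = bnc[c("xhat", "s")], act = bnc$y > 0)
      }
    }
    decCaches[[i]] <- blkCache
  }
  probs <- .softmaxProbs(x)
  out <- list(probs = probs)
  if (!is.null(labels)) {
    d <- dim(probs); npx <- prod(d[1:2])
    pm <- matrix(probs, npx, d[3L])
    yi <- as.integer(labels) + 1L
    w <- if (is.null(classWeights)) rep(1, npx) else classWeights[yi]
    sw <- sum(w)
    out$loss <- -sum(w * log(pmax(pm[cbind(seq_len(npx), yi)], 1e-12))) / sw
    if (wantGrad) {
      Y <- matrix(0, npx, d[3L]); Y[cbind(seq_len(npx), yi)] <- 1
      dx <- array(w * (pm - Y) / sw, d)
      gDec <- vector("list", nb); gEnc <- vector("list", nb)
      for (i in nb:1) {
        b <- nb - i + 1L
        blkG <- list()
        for (l in rev(seq_along(params$decoder[[i]]))) {
          cp <- params$decoder[[i]][[l]]; cc <- decCaches[[i]][[l]]
          if (is.null(cc$bn)) {
            cb <- .convBackward(dx, cc$xp, cp$W)
            blkG[[l]] <- list(W = cb$dW, b = cb$db)
          } else {
            dx <- dx * cc$act
            bb <- .bnBackward(dx, cc$bn, cp$g)
            cb <- .convBackward(bb$dx, cc$xp, cp$W)
            blkG[[l]] <- list(W = cb$dW, b = cb$db, g = bb$dg, be = bb$dbe)
          }
          dx <- cb$dx
        }
        gDec[[i]] <- blkG
        dx <- .unpoolBackward(dx, poolCaches[[nb - i + 1L]])
      }
      for (b in nb:1) {
        dx <- .poolBackward(dx, poolCaches[[b]])
        blkG <- list()
        for (l in rev(seq_along(params$encoder[[b]]))) {
          cp <- params$encoder[[b]][[l]]; cc <- encCaches[[b]][[l]]
          dx <- dx * cc$act
          bb <- .bnBackward(dx, cc$bn, cp$g)
          cb <- .convBackward(bb$dx, cc$xp, cp$W)
          blkG[[l]] <- list(W = cb$dW, b = cb$db, g = bb$dg, be = bb$dbe)
          dx <- cb$dx
        }
        gEnc[[b]] <- blkG
      }
      out$grads <- list(encoder = gEnc, decoder = gDec)
    }
  }
  out
}

## decoder i unpools with the pool indices of encoder block nb - i + 1; in the
## backward pass the order reverses, handled above.

.asInputArray <- function(image, inChannels) {
  if (length(dim(image)) == 2L)
    array(rep(as.numeric(image), inChannels), c(dim(image), inChannels))
  else image
}

## elementwise recursion over congruent nested parameter lists
.mapParams <- function(f, a, b = NULL) {
  if (is.list(a) && !is.null(a$W) && is.array(a$W)) {
    out <- lapply(names(a), function(nm) f(a[[nm]], if (is.null(b)) NULL else b[[nm]]))
    names(out) <- names(a)
    out
  } else {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .mapParams(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    out
  }
}

## ---- training -------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the published recipe: SGD with momentum 0.9, learning rate
#' 1e-2, mini-batches of 4 observations and up to 120 epochs. Desk-scale
#' experiments reduce `maxEpochs` (the phantom task converges in a few
#' epochs).
#'
#' @param momentum in `[0, 1)`.
#' @param learningRate positive step size.
#' @param maxEpochs maximum epochs (>= 1).
#' @param miniBatch observations per gradient step (>= 1).
#' @param seed RNG seed (shuffling).
#' @param classWeights `NULL` for unweighted per-pixel cross-entropy,
#'   `"balanced"` for median-frequency class balancing (weights computed from
#'   the training labels), or a numeric vector of per-class weights. Weighting
#'   is needed for the multi-class whole-limb model, where the rare bone
#'   classes otherwise contribute vanishing gradient mass.
#' @return List of class `"TrainConfig"`.
#' @export
trainConfig <- function(momentum = 0.9, learningRate = 1e-2, maxEpochs = 120,
                        miniBatch = 4, seed = 1, classWeights = NULL) {
  if (momentum < 0 || momentum >= 1) .laStop("limbAlign_config_error", "momentum must be in [0, 1)")
  if (learningRate < 0) .laStop("limbAlign_config_error", "learningRate must be >= 0")
  if (maxEpochs < 1 || miniBatch < 1) .laStop("limbAlign_config_error", "epochs and batch must be >= 1")
  structure(list(solver = "sgd_momentum", momentum = momentum,
                 learningRate = learningRate, maxEpochs = as.integer(maxEpochs),
                 miniBatch = as.integer(miniBatch), seed = seed,
                 classWeights = classWeights),
            class = "TrainConfig")
}

#' Train a segmentation model
#'
#' Minimises the unweighted per-pixel cross-entropy with SGD momentum,
#' recording per-epoch training and validation loss and keeping the
#' parameters with the best validation loss (final parameters if no
#' validation set is given). Deterministic given `cfg$seed` and single-
#' threaded numerics.
#'
#' @param model an untrained or trained [SegModel-class].
#' @param images list of input rasters (values in `[0, 1]`), all at the same
#'   size; grayscale inputs are replicated to the model's channel count.
#' @param labels list of label matrices (0 = background, values <
#'   `model@classes`).
#' @param cfg a [trainConfig()].
#' @param valImages,valLabels optional validation split.
#' @return The trained [SegModel-class] (see [trainingHistory()]).
#' @export
trainSegModel <- function(model, images, labels, cfg = trainConfig(),
                          valImages = NULL, valLabels = NULL) {
  stopifnot(is(model, "SegModel"), length(images) == length(labels), length(images) > 0)
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(cfg$seed)
  params <- model@params
  vel <- .mapParams(function(w, .) if (is.null(dim(w))) numeric(length(w)) else array(0, dim(w)),
                    params)
  n <- length(images)
  cw <- cfg$classWeights
  if (identical(cw, "balanced")) {
    freq <- table(factor(unlist(lapply(labels, as.integer)),
                         levels = 0:(model@classes - 1L)))
    freq <- as.numeric(freq) / sum(freq)
    cw <- stats::median(freq[freq > 0]) / pmax(freq, 1e-12)   # median-frequency balancing
  }
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))
  best <- list(loss = Inf, params = params)
  evalLoss <- function(p, ims, labs) {
    mean(vapply(seq_along(ims), function(i) {
      .segForward(p, .asInputArray(ims[[i]], model@config$inChannels), labs[[i]],
                  classWeights = cw)$loss
    }, numeric(1)))
  }
  for (epoch in seq_len(cfg$maxEpochs)) {
    ord <- sample.int(n)
    lossSum <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$miniBatch)) {
      batch <- ord[start:min(start + cfg$miniBatch - 1L, n)]
      gAcc <- NULL
      for (i in batch) {
        fw <- .segForward(params, .asInputArray(images[[i]], model@config$inChannels),
                          labels[[i]], wantGrad = TRUE, classWeights = cw)
        lossSum <- lossSum + fw$loss; nb <- nb + 1L
        gAcc <- if (is.null(gAcc)) fw$grads
                else .mapParams(`+`, gAcc, fw$grads)
      }
      scale <- cfg$learningRate / length(batch)
      vel <- .mapParams(function(v, g) cfg$momentum * v - scale * g, vel, gAcc)
      params <- .mapParams(`+`, params, vel)
    }
    trainLoss <- lossSum / nb
    valLoss <- if (!is.null(valImages)) evalLoss(params, valImages, valLabels) else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = trainLoss, val_loss = valLoss))
    if (!is.finite(trainLoss))
      .laStop("limbAlign_training_diverged", "training loss diverged", history = hist)
    track <- if (is.na(valLoss)) trainLoss else valLoss
    if (track < best$loss) best <- list(loss = track, params = params)
  }
  model@params <- if (is.null(valImages) ) params else best$params
  model@trained <- TRUE
  model@history <- hist
  model
}

#' Save / load a segmentation model checkpoint
#'
#' The checkpoint is the full [SegModel-class] object (architecture
#' descriptor, parameters, initialisation seed and training history), so a
#' loaded model is self-describing and immediately usable.
#'
#' @param model a [SegModel-class].
#' @param path checkpoint file path (`.rds`).
#' @return `readSegModel`: the restored [SegModel-class].
#' @export
saveSegModel <- function(model, path) {
  stopifnot(is(model, "SegModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveSegModel
#' @export
readSegModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "SegModel")) .laStop("limbAlign_config_error", "not a SegModel checkpoint")
  m
}

#' Predict class probabilities per pixel
#'
#' @param model a [SegModel-class].
#' @param image raster at the model's input size, values in `[0, 1]`.
#' @return Array H x W x classes of per-pixel probabilities (summing to 1).
#' @export
predictProbs <- function(model, image) {
  .segForward(model@params, .asInputArray(image, model@config$inChannels))$probs
}

#' Predict a label raster (argmax over classes)
#'
#' @inheritParams predictProbs
#' @return Integer matrix of class labels, 0 = background.
#' @export
predictLabels <- function(model, image) {
  p <- predictProbs(model, image)
  d <- dim(p)
  matrix(max.col(matrix(p, prod(d[1:2]), d[3L]), ties.method = "first") - 1L, d[1L], d[2L])
}

#' Predict a binary mask with standard post-processing
#'
#' Argmax over classes, then keep the largest connected foreground component
#' and fill interior holes.
#'
#' @inheritParams predictProbs
#' @return Binary integer matrix.
#' @export
predictMask <- function(model, image) {
  lab <- predictLabels(model, image) > 0
  if (!any(lab)) return(matrix(0L, nrow(lab), ncol(lab)))
  comp <- .largestComponent(lab)
  filled <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(comp * 1)))))
  matrix(as.integer(filled > 0), nrow(lab), ncol(lab))
}
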