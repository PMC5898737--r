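#' 3-level volumetric U-Net architecture configuration
#'
#' The default architecture: an encoding path of two levels of paired
#' same-padded 3x3x3 convolutions + ReLU followed by 2x2x2 max-pooling
#' (stride 2) with channel doubling from 16, a two-convolution bottleneck,
#' a decoding path of nearest-neighbour upsampling + 3x3x3 "up-convolution"
#' halving the channels, concatenation with the matching encoder feature
#' map and two further convolutions, and a final 1x1x1 convolution to a
#' single sigmoid foreground channel. No batch normalization. This
#' configuration has 11 convolution layers (the ten block convolutions plus
#' the final 1x1x1; up-convolutions count as part of upsampling) and
#' 387,889 trainable parameters.
#'
#' @param nLevels number of resolution levels (encoder levels plus
#'   bottleneck), default 3 (two down-samplings).
#' @param baseChannels feature channels at the first level, default 16.
#' @param inChannels input channels, default 1.
#' @param outChannels output channels, default 1 (sigmoid foreground
#'   probability).
#' @return List of class \code{"unetConfig"}.
#' @examples
#' countParameters(unetConfig())  # 387889
#' @export
unetConfig <- function(nLevels = 3L, baseChannels = 16L, inChannels = 1L,
                       outChannels = 1L) {
  stopifnot(nLevels >= 2, baseChannels >= 1, inChannels >= 1, outChannels >= 1)
  structure(list(nLevels = as.integer(nLevels),
                 baseChannels = as.integer(baseChannels),
                 inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels)),
            class = "unetConfig")
}

# Ordered description of every convolution: name, kernel size, channels.
convPlan <- function(cfg) {
  L <- cfg$nLevels
  ch <- cfg$baseChannels * 2^(seq_len(L) - 1)
  plan <- list()
  add <- function(name, k, cin, cout)
    plan[[name]] <<- list(k = k, cin = cin, cout = cout)
  for (l in seq_len(L - 1)) {
    add(sprintf("enc%d_conv1", l), 3L, if (l == 1) cfg$inChannels else ch[l - 1], ch[l])
    add(sprintf("enc%d_conv2", l), 3L, ch[l], ch[l])
  }
  add("bott_conv1", 3L, ch[L - 1], ch[L])
  add("bott_conv2", 3L, ch[L], ch[L])
  for (l in rev(seq_len(L - 1))) {
    add(sprintf("up%d", l), 3L, ch[l + 1], ch[l])
    add(sprintf("dec%d_conv1", l), 3L, 2L * ch[l], ch[l])
    add(sprintf("dec%d_conv2", l), 3L, ch[l], ch[l])
  }
  add("final", 1L, ch[1], cfg$outChannels)
  plan
}

#' Closed-form trainable parameter count
#'
#' Sums \eqn{k^3 c_{in} c_{out} + c_{out}} (weights plus biases) over every
#' convolution of the architecture, including the two up-convolutions and
#' the final 1x1x1 head. Provably equal to the built network's total.
#'
#' @param cfg a \code{\link{unetConfig}}.
#' @return Integer parameter count; 387,889 for the default configuration.
#' @export
countParameters <- function(cfg = unetConfig()) {
  as.integer(sum(vapply(convPlan(cfg), function(p)
    p$k^3 * p$cin * p$cout + p$cout, numeric(1))))
}

#' Convolution-layer count under the reporting convention
#'
#' Counts the per-block 3x3x3 convolutions and the final 1x1x1 convolution;
#' up-convolutions are counted as part of the upsampling step rather than
#' as convolution layers. The default architecture reports 11.
#'
#' @param cfg a \code{\link{unetConfig}}.
#' @return Integer layer count.
#' @export
countConvLayers <- function(cfg = unetConfig()) {
  nm <- names(convPlan(cfg))
  as.integer(sum(!grepl("^up", nm)))
}

#' Build a randomly initialized 3D U-Net
#'
#' Weights use the fan-in-scaled uniform scheme
#' (limit \eqn{\sqrt{6 / (k^3 c_{in})}}); biases start at zero.
#'
#' @param cfg a \code{\link{unetConfig}}.
#' @param seed integer seed for the initialization.
#' @return A \code{\linkS4class{UNet3D}}.
#' @export
buildUnet <- function(cfg = unetConfig(), seed = 1L) {
  plan <- convPlan(cfg)
  weights <- withSeed(seed, function()
    lapply(plan, function(p) {
      fanIn <- p$k^3 * p$cin
      lim <- sqrt(6 / fanIn)
      list(W = matrix(runif(fanIn * p$cout, -lim, lim), fanIn, p$cout),
           b = numeric(p$cout), k = p$k)
    }))
  new("UNet3D", config = unclass(cfg), weights = weights)
}

#' Total parameters of a built network
#'
#' @param net a \code{\linkS4class{UNet3D}}.
#' @return Integer count of weight and bias entries actually stored.
#' @export
networkParameterCount <- function(net) {
  as.integer(sum(vapply(net@weights, function(w)
    length(w$W) + length(w$b), numeric(1))))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

asInputArray <- function(x) {
  if (is(x, "BrainVolume")) x <- x@data
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

checkInputShape <- function(cfg, d) {
  fac <- 2^(cfg$nLevels - 1)
  if (any(d[1:3] %% fac != 0))
    stop("input shape (", paste(d[1:3], collapse = "x"),
         ") must be divisible by ", fac, " on each axis")
}

# Forward pass; with cache = TRUE also returns everything the backward
# pass needs (conv inputs, pre-activations, pooling argmaxes).
unetForward <- function(net, x, cache = FALSE) {
  cfg <- net@config
  L <- cfg$nLevels
  x <- asInputArray(x)
  checkInputShape(cfg, dim(x))
  W <- net@weights
  cc <- list(convIn = list(), preact = list(), poolArg = list(),
             poolInDim = list(), upInDim = list())
  convRelu <- function(cur, name) {
    if (cache) cc$convIn[[name]] <<- cur
    pre <- cpp_conv3d_fwd(as.numeric(cur), dim(cur), W[[name]]$W,
                          W[[name]]$b, W[[name]]$k)
    if (cache) cc$preact[[name]] <<- pre
    relu(pre)
  }
  skips <- list()
  cur <- x
  for (l in seq_len(L - 1)) {
    cur <- convRelu(cur, sprintf("enc%d_conv1", l))
    cur <- convRelu(cur, sprintf("enc%d_conv2", l))
    skips[[l]] <- cur
    mp <- cpp_maxpool_fwd(as.numeric(cur), dim(cur))
    if (cache) {
      cc$poolArg[[l]] <- mp$argmax
      cc$poolInDim[[l]] <- dim(cur)
    }
    cur <- mp$out
  }
  cur <- convRelu(cur, "bott_conv1")
  cur <- convRelu(cur, "bott_conv2")
  for (l in rev(seq_len(L - 1))) {
    if (cache) cc$upInDim[[l]] <- dim(cur)
    up <- cpp_upsample_fwd(as.numeric(cur), dim(cur))
    cur <- convRelu(up, sprintf("up%d", l))
    cat4 <- array(c(skips[[l]], cur),
                  c(dim(cur)[1:3], dim(skips[[l]])[4] + dim(cur)[4]))
    cur <- convRelu(cat4, sprintf("dec%d_conv1", l))
    cur <- convRelu(cur, sprintf("dec%d_conv2", l))
  }
  name <- "final"
  if (cache) cc$convIn[[name]] <- cur
  logits <- cpp_conv3d_fwd(as.numeric(cur), dim(cur), W[[name]]$W,
                           W[[name]]$b, W[[name]]$k)
  prob <- 1 / (1 + exp(-logits))
  out <- list(prob = prob, logits = logits)
  if (cache) out$cache <- cc
  out
}

# Backward pass from d(loss)/d(logits); returns per-layer gradients.
unetBackward <- function(net, cache, dLogits) {
  cfg <- net@config
  L <- cfg$nLevels
  W <- net@weights
  grads <- list()
  convBwd <- function(dact, name, throughRelu = TRUE) {
    dpre <- if (throughRelu) dact * (cache$preact[[name]] > 0) else dact
    xin <- cache$convIn[[name]]
    g <- cpp_conv3d_bwd(as.numeric(xin), dim(xin), W[[name]]$W,
                        as.numeric(dpre), W[[name]]$k)
    grads[[name]] <<- list(dW = g$dW, db = g$db)
    g$dx
  }
  dcur <- convBwd(dLogits, "final", throughRelu = FALSE)
  dskips <- list()
  for (l in seq_len(L - 1)) {  # decoder levels, innermost-first is l = 1
    dcur <- convBwd(dcur, sprintf("dec%d_conv2", l))
    dcat <- convBwd(dcur, sprintf("dec%d_conv1", l))
    nSkip <- dim(dcat)[4] / 2
    dskips[[l]] <- dcat[, , , seq_len(nSkip), drop = FALSE]
    dup <- dcat[, , , nSkip + seq_len(nSkip), drop = FALSE]
    dupin <- convBwd(dup, sprintf("up%d", l))
    dcur <- cpp_upsample_bwd(as.numeric(dupin), cache$upInDim[[l]])
  }
  dcur <- convBwd(dcur, "bott_conv2")
  dcur <- convBwd(dcur, "bott_conv1")
  for (l in rev(seq_len(L - 1))) {
    dcur <- cpp_maxpool_bwd(as.numeric(dcur), cache$poolArg[[l]],
                            cache$poolInDim[[l]])
    dcur <- dcur + dskips[[l]]
    dcur <- convBwd(dcur, sprintf("enc%d_conv2", l))
    dcur <- convBwd(dcur, sprintf("enc%d_conv1", l))
  }
  grads
}

#' Soft Dice loss
#'
#' The negative soft (probabilistic) Dice similarity coefficient,
#' \deqn{-\frac{2\sum p t + s}{\sum p + \sum t + s},}
#' the quantity backpropagated during training. It lies in [-1, 0] and
#' equals \code{-dsc(P, T)} exactly for binary \code{prob} and
#' \code{smooth = 0}.
#'
#' @param prob probability volume (array or \code{BrainVolume}) in [0, 1].
#' @param truth binary reference (array or \code{BrainMask}).
#' @param smooth small stabilizing constant, default 1e-6.
#' @return Scalar loss.
#' @examples
#' t <- array(c(1, 0), c(2, 2, 2))
#' diceLoss(t, t)  # ~ -1
#' @export
diceLoss <- function(prob, truth, smooth = 1e-6) {
  p <- if (is(prob, "BrainVolume")) prob@data else prob
  t <- if (is(truth, "BrainVolume")) truth@data else truth
  if (!identical(dim(p)[1:3], dim(t)[1:3]) || length(p) != length(t))
    stop("probability and truth shapes differ")
  p <- as.numeric(p); t <- as.numeric(t)
  -(2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

# Gradient of diceLoss with respect to prob.
diceLossGrad <- function(p, t, smooth = 1e-6) {
  D <- sum(p) + sum(t) + smooth
  L <- -(2 * sum(p * t) + smooth) / D
  (-2 * t - L) / D
}

hardDice <- function(p, t, threshold = 0.5) {
  P <- p >= threshold
  T <- t > 0
  denom <- sum(P) + sum(T)
  if (denom == 0) return(1)
  2 * sum(P & T) / denom
}

#' Training hyperparameters
#'
#' Defaults follow the study protocol: Adam with learning rate 1e-4,
#' batch size 5, up to 150 epochs, minus soft Dice as the loss.
#'
#' @param learningRate Adam step size, default 1e-4.
#' @param batchSize minibatch size, default 5.
#' @param maxEpochs maximum training epochs, default 150.
#' @param seed integer seed governing shuffling and augmentation.
#' @param smooth Dice smoothing constant.
#' @return List of class \code{"trainConfig"}.
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 5L,
                        maxEpochs = 150L, seed = 1L, smooth = 1e-6) {
  stopifnot(learningRate > 0, batchSize >= 1, maxEpochs >= 0)
  structure(list(learningRate = learningRate, batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs), seed = as.integer(seed),
                 smooth = smooth),
            class = "trainConfig")
}

#' Train the U-Net with Adam and Dice loss
#'
#' Mini-batch optimization of minus soft Dice, with optional on-the-fly
#' affine augmentation of the training subjects only (a fresh transform
#' per epoch and subject, seeded deterministically). Per-epoch training
#' loss and Dice plus validation loss, hard Dice (probability threshold
#' 0.5) and soft Dice are recorded. Returns final-epoch weights.
#'
#' @param net a \code{\linkS4class{UNet3D}}.
#' @param trainSubjects,valSubjects lists of \code{list(x =, y =)} with the
#'   preprocessed input volume and binary target (arrays, or
#'   \code{BrainVolume}/\code{BrainMask}).
#' @param cfg a \code{\link{trainConfig}}.
#' @param aug an \code{\link{augmentParams}}, or \code{NULL} for no
#'   augmentation.
#' @param verbose print per-epoch progress.
#' @return \code{list(net, history)}; \code{history} is a data frame with
#'   one row per completed epoch.
#' @export
trainUnet <- function(net, trainSubjects, valSubjects = list(),
                      cfg = trainConfig(), aug = NULL, verbose = FALSE) {
  if (length(trainSubjects) == 0) stop("empty training set")
  toArr <- function(s) list(
    x = asInputArray(s$x),
    y = { y <- if (is(s$y, "BrainVolume")) s$y@data else s$y
          if (length(dim(y)) == 3L) dim(y) <- c(dim(y), 1L)
          y })
  tr <- lapply(trainSubjects, toArr)
  va <- lapply(valSubjects, toArr)
  emptyHist <- data.frame(epoch = integer(), trainLoss = numeric(),
                          trainDice = numeric(), valLoss = numeric(),
                          valDice = numeric(), valSoftDice = numeric())
  if (cfg$maxEpochs == 0) return(list(net = net, history = emptyHist))

  plan <- names(net@weights)
  adam <- lapply(net@weights, function(w)
    list(mW = 0 * w$W, vW = 0 * w$W, mb = 0 * w$b, vb = 0 * w$b))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  hist <- vector("list", cfg$maxEpochs)

  withSeed(cfg$seed, function() {
    for (epoch in seq_len(cfg$maxEpochs)) {
      ord <- sample(length(tr))
      epLoss <- c(); epDice <- c()
      for (chunk in split(ord, ceiling(seq_along(ord) / cfg$batchSize))) {
        gacc <- NULL
        for (i in chunk) {
          s <- tr[[i]]
          if (!is.null(aug)) {
            d3 <- dim(s$x)[1:3]
            a <- augmentPair(
              brainVolume(array(s$x, d3)),
              brainMask(array(s$y, d3)),
              aug, seed = deriveSeed(deriveSeed(cfg$seed, epoch), i))
            s <- list(x = asInputArray(a$volume@data),
                      y = asInputArray(a$mask@data))
          }
          fw <- unetForward(net, s$x, cache = TRUE)
          loss <- diceLoss(fw$prob, s$y, cfg$smooth)
          if (!is.finite(loss))
            stop("non-finite loss at epoch ", epoch)
          epLoss <- c(epLoss, loss)
          epDice <- c(epDice, hardDice(fw$prob, s$y))
          dprob <- diceLossGrad(fw$prob, s$y, cfg$smooth)
          dlogits <- dprob * fw$prob * (1 - fw$prob)
          g <- unetBackward(net, fw$cache, dlogits)
          if (is.null(gacc)) gacc <- g
          else for (nm in plan) {
            gacc[[nm]]$dW <- gacc[[nm]]$dW + g[[nm]]$dW
            gacc[[nm]]$db <- gacc[[nm]]$db + g[[nm]]$db
          }
        }
        nb <- length(chunk)
        t <<- t + 1
        for (nm in plan) {
          dW <- gacc[[nm]]$dW / nb; db <- gacc[[nm]]$db / nb
          st <- adam[[nm]]
          st$mW <- b1 * st$mW + (1 - b1) * dW
          st$vW <- b2 * st$vW + (1 - b2) * dW^2
          st$mb <- b1 * st$mb + (1 - b1) * db
          st$vb <- b2 * st$vb + (1 - b2) * db^2
          adam[[nm]] <<- st
          mhW <- st$mW / (1 - b1^t); vhW <- st$vW / (1 - b2^t)
          mhb <- st$mb / (1 - b1^t); vhb <- st$vb / (1 - b2^t)
          w <- net@weights[[nm]]
          w$W <- w$W - cfg$learningRate * mhW / (sqrt(vhW) + eps)
          w$b <- w$b - cfg$learningRate * mhb / (sqrt(vhb) + eps)
          net@weights[[nm]] <<- w
        }
      }
      vl <- vd <- vs <- NA_real_
      if (length(va)) {
        losses <- dices <- softs <- numeric(length(va))
        for (i in seq_along(va)) {
          fw <- unetForward(net, va[[i]]$x)
          losses[i] <- diceLoss(fw$prob, va[[i]]$y, cfg$smooth)
          dices[i] <- hardDice(fw$prob, va[[i]]$y)
          softs[i] <- -losses[i]
        }
        vl <- mean(losses); vd <- mean(dices); vs <- mean(softs)
      }
      hist[[epoch]] <<- data.frame(epoch = epoch, trainLoss = mean(epLoss),
                                   trainDice = mean(epDice), valLoss = vl,
                                   valDice = vd, valSoftDice = vs)
      if (verbose)
        message(sprintf("epoch %d: train loss %.4f dice %.4f | val dice %s",
                        epoch, mean(epLoss), mean(epDice),
                        ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
    }
  })
  list(net = net, history = do.call(rbind, hist))
}

#' Predict a probability map and binary mask
#'
#' @param net a trained \code{\linkS4class{UNet3D}}.
#' @param v preprocessed input (\code{BrainVolume} or 3D array) whose shape
#'   is divisible by the architecture's pooling factor.
#' @param probThreshold probability cut for the binary mask (inclusive),
#'   default 0.5.
#' @return \code{list(prob, mask)}: the sigmoid probability
#'   \code{BrainVolume} and the thresholded \code{BrainMask}.
#' @export
predictMask <- function(net, v, probThreshold = 0.5) {
  sp <- if (is(v, "BrainVolume")) v@spacing else c(1, 1, 1)
  ax <- if (is(v, "BrainVolume")) v@lrAxis else 1L
  fw <- unetForward(net, v)
  d3 <- dim(fw$prob)[1:3]
  prob <- array(fw$prob, d3)
  list(prob = brainVolume(prob, spacing = sp, lrAxis = ax),
       mask = brainMask((prob >= probThreshold) * 1, spacing = sp,
                        lrAxis = ax))
}

#' Save / load a trained network
#'
#' Weights go to an RDS checkpoint; a JSON sidecar records the
#' architecture configuration and parameter count.
#'
#' @param net a \code{\linkS4class{UNet3D}}.
#' @param dir destination directory (created if needed).
#' @return \code{saveUnet}: invisibly, \code{dir}; \code{loadUnet}: the
#'   restored \code{UNet3D}.
#' @export
saveUnet <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(net@weights, file.path(dir, "weights.rds"))
  jsonlite::write_json(
    list(config = net@config, nParameters = networkParameterCount(net)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveUnet
#' @export
loadUnet <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "model.json"))
  cfg <- do.call(unetConfig, side$config)
  new("UNet3D", config = unclass(cfg),
      weights = readRDS(file.path(dir, "weights.rds")))
}
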