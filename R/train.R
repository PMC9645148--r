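#' @include esa-unet.R
NULL

# Cross-entropy + soft-Dice loss and its gradient w.r.t. the logits.
# `mask` holds labels 0..K-1. Dice is averaged over foreground classes.
# CE is computed from the logits via log-sum-exp, which keeps the loss and
# its gradient exact even where the softmax saturates.
.segLoss <- function(probs, logits, mask, diceEps = 1) {
  d <- dim(probs)
  n <- d[1L] * d[2L]
  K <- d[3L]
  pm <- matrix(probs, n, K)
  lm <- matrix(logits, n, K)
  oh <- matrix(0, n, K)
  oh[cbind(seq_len(n), as.integer(mask) + 1L)] <- 1
  mx <- apply(lm, 1L, max)
  lse <- mx + log(rowSums(exp(lm - mx)))
  ce <- mean(lse - lm[oh == 1])
  fg <- 2:K
  inter <- colSums(pm[, fg, drop = FALSE] * oh[, fg, drop = FALSE])
  tot <- colSums(pm[, fg, drop = FALSE]) + colSums(oh[, fg, drop = FALSE])
  dicePerClass <- (2 * inter + diceEps) / (tot + diceEps)
  diceLoss <- 1 - mean(dicePerClass)
  # Dice gradient w.r.t. probabilities (quotient rule), then through the
  # per-pixel softmax; the CE gradient is the classic (softmax - onehot).
  dLdp <- matrix(0, n, K)
  for (j in seq_along(fg)) {
    k <- fg[j]
    dDk <- (2 * oh[, k] * (tot[j] + diceEps) - (2 * inter[j] + diceEps)) /
      (tot[j] + diceEps)^2
    dLdp[, k] <- -dDk / length(fg)
  }
  inner <- rowSums(dLdp * pm)
  dlogits <- (pm - oh) / n + pm * (dLdp - inner)
  list(loss = ce + diceLoss, ce = ce, dice = diceLoss,
       dlogits = array(dlogits, d))
}

#' Mean foreground Dice of a prediction against a reference mask
#'
#' Hard Dice per foreground class (right atrium, left atrium, aorta),
#' averaged; classes empty in both maps count as 1.
#'
#' @param pred,ref Integer label matrices over 0..K-1.
#' @param numClasses Number of classes K.
#' @return Mean Dice over foreground classes.
#' @export
foregroundDice <- function(pred, ref, numClasses = 4L) {
  mean(vapply(seq_len(numClasses - 1L), function(k) {
    a <- pred == k; b <- ref == k
    denom <- sum(a) + sum(b)
    if (denom == 0) 1 else 2 * sum(a & b) / denom
  }, numeric(1)))
}

# Random flip / small-angle rotation augmentation (nearest neighbour;
# rotation leaves out-of-range pixels at the background label/intensity 0).
.augmentSample <- function(img, mask, maxDeg = 15) {
  if (stats::runif(1) < 0.5) {
    img <- img[rev(seq_len(nrow(img))), ]
    mask <- mask[rev(seq_len(nrow(mask))), ]
  }
  if (stats::runif(1) < 0.5) {
    img <- img[, rev(seq_len(ncol(img)))]
    mask <- mask[, rev(seq_len(ncol(mask)))]
  }
  deg <- stats::runif(1, -maxDeg, maxDeg)
  if (abs(deg) > 0.5) {
    th <- deg * pi / 180
    h <- nrow(img); w <- ncol(img)
    cr <- (h + 1) / 2; cc <- (w + 1) / 2
    rr <- matrix(seq_len(h), h, w) - cr
    cc2 <- matrix(seq_len(w), h, w, byrow = TRUE) - cc
    sr <- round(cr + cos(th) * rr - sin(th) * cc2)
    sc <- round(cc + sin(th) * rr + cos(th) * cc2)
    ok <- as.vector(sr >= 1 & sr <= h & sc >= 1 & sc <= w)
    idx <- cbind(as.vector(pmin(pmax(sr, 1), h)),
                 as.vector(pmin(pmax(sc, 1), w)))
    ni <- matrix(0, h, w); nm <- matrix(0L, h, w)
    ni[ok] <- img[idx[ok, , drop = FALSE]]
    nm[ok] <- mask[idx[ok, , drop = FALSE]]
    img <- ni; mask <- nm
  }
  list(img = img, mask = mask)
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the segmentation network
#'
#' Minimizes cross-entropy plus soft Dice with Adam, accumulating
#' gradients over mini-batches. Deterministic for a fixed \code{seed} on a
#' given BLAS. Aborts with a diagnostic on an empty dataset or a
#' non-finite loss.
#'
#' @param model An \code{\link{esaUNet}}.
#' @param images List of H x W intensity matrices (normalized crops).
#' @param maskList List of matching integer label matrices.
#' @param valImages,valMasks Optional held-out pairs; per-epoch validation
#'   mean foreground Dice is logged when given.
#' @param epochs Number of passes over the data.
#' @param lr Adam learning rate.
#' @param batchSize Gradient-accumulation batch size.
#' @param augment Apply random flips and up-to-15-degree rotations.
#' @param seed RNG seed controlling shuffling and augmentation.
#' @param checkpointPath If non-NULL, the best-validation model is saved
#'   there (RDS) whenever validation Dice improves.
#' @param verbose Print a line per epoch.
#' @return List with the trained \code{model} and a \code{log} data.frame
#'   (epoch, loss, ce, dice, valDSC).
#' @export
trainESAUNet <- function(model, images, maskList,
                         valImages = NULL, valMasks = NULL,
                         epochs = 12L, lr = 1e-3, batchSize = 4L,
                         augment = FALSE, seed = 1L,
                         checkpointPath = NULL, verbose = FALSE) {
  if (length(images) == 0L) stop("empty training dataset")
  if (length(images) != length(maskList))
    stop("images and masks must pair up")
  state <- .adamInit(model$params)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    ce = numeric(0), dice = numeric(0),
                    valDSC = numeric(0))
  bestVal <- -Inf
  .withSeed(.subSeed(seed, 17L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(images))
      epLoss <- epCe <- epDice <- 0
      nb <- 0L
      i <- 1L
      while (i <= length(ord)) {
        take <- ord[i:min(i + batchSize - 1L, length(ord))]
        i <- i + batchSize
        acc <- NULL
        bl <- 0
        for (j in take) {
          img <- images[[j]]; mk <- maskList[[j]]
          if (augment) {
            au <- .augmentSample(img, mk)
            img <- au$img; mk <- au$mask
          }
          fwd <- .netFwd(model, img)
          ls <- .segLoss(fwd$probs, fwd$logits, mk)
          if (!is.finite(ls$loss))
            stop("non-finite loss at epoch ", ep, ", sample ", j,
                 "; aborting training")
          g <- .netBwd(model, fwd, ls$dlogits)
          acc <- if (is.null(acc)) g else
            Map(`+`, acc, g[names(acc)])
          bl <- bl + ls$loss
          epCe <- epCe + ls$ce; epDice <- epDice + ls$dice
        }
        acc <- lapply(acc, function(a) a / length(take))
        up <- .adamStep(model$params, acc, state, lr = lr)
        model$params <- up$params
        state <- up$state
        epLoss <- epLoss + bl
        nb <- nb + length(take)
      }
      valDSC <- NA_real_
      if (!is.null(valImages)) {
        valDSC <- mean(vapply(seq_along(valImages), function(j) {
          pr <- predictProbs(model, valImages[[j]])
          foregroundDice(probsToMask(pr), valMasks[[j]],
                         model$config$numClasses)
        }, numeric(1)))
        if (!is.null(checkpointPath) && valDSC > bestVal) {
          bestVal <- valDSC
          saveRDS(model, checkpointPath)
        }
      }
      log[nrow(log) + 1L, ] <- list(ep, epLoss / nb, epCe / nb,
                                    epDice / nb, valDSC)
      if (verbose)
        message(sprintf("epoch %2d  loss %.4f  (ce %.4f, dice %.4f)  valDSC %s",
                        ep, epLoss / nb, epCe / nb, epDice / nb,
                        ifelse(is.na(valDSC), "-", sprintf("%.3f", valDSC))))
    }
  })
  list(model = model, log = log)
}

#' Build the standard small phantom training set
#'
#' Generates \code{nPhantoms} phantoms at the generator defaults, detects
#' the ROI in each, crops the 128 x 128 aorta-centred window, box-downsamples
#' it to 64 x 64 (the package's training resolution) and takes
#' \code{framesPer} evenly spaced frames per phantom. The split is by
#' phantom so no cardiac cycle leaks across train and validation.
#'
#' @param seed Base seed; phantom k uses seed \code{seed * 100 + k}.
#' @param nPhantoms Number of phantoms (25 gives 100 crops).
#' @param framesPer Frames kept per phantom.
#' @param valPhantoms Number of phantoms held out for validation.
#' @return List with \code{train} and \code{val}, each a list of
#'   \code{images} and \code{masks}.
#' @export
phantomTrainingSet <- function(seed = 1L, nPhantoms = 25L, framesPer = 4L,
                               valPhantoms = 5L) {
  trImg <- list(); trMsk <- list()
  vaImg <- list(); vaMsk <- list()
  for (k in seq_len(nPhantoms)) {
    sp <- phantomSpec(seed = seed * 100L + k)
    cs <- generatePhantom(sp)
    roi <- detectROI(cs)
    cr <- cropAndNormalize(cs, roi)
    tt <- round(seq(1, nFrames(cr), length.out = framesPer))
    isVal <- k > nPhantoms - valPhantoms
    for (t in tt) {
      img <- .downsample2(frames(cr)[, , t])
      mk <- masks(cr)[seq(1L, 128L, 2L), seq(1L, 128L, 2L), t]
      if (isVal) {
        vaImg[[length(vaImg) + 1L]] <- img
        vaMsk[[length(vaMsk) + 1L]] <- mk
      } else {
        trImg[[length(trImg) + 1L]] <- img
        trMsk[[length(trMsk) + 1L]] <- mk
      }
    }
  }
  list(train = list(images = trImg, masks = trMsk),
       val = list(images = vaImg, masks = vaMsk))
}

#' Run the standard small training benchmark
#'
#' The package's reference scaled-down experiment: 25 default phantoms
#' yield 80 training and 20 validation crops at 64 x 64; an 8-channel-base
#' network trains for 12 epochs with Adam at 1e-3 (batch 4). Returns the
#' trained model, the training log and the final validation mean
#' foreground Dice.
#'
#' @param seed Seed controlling data generation, initialization and
#'   shuffling.
#' @param useLRSAR \code{FALSE} trains the plain U-Net ablation under the
#'   identical budget.
#' @param epochs,baseChannels,lr,batchSize Overridable run parameters.
#' @param data Optionally a precomputed \code{\link{phantomTrainingSet}}
#'   (so the LRSAR and ablation runs can share one dataset).
#' @param verbose Print per-epoch progress.
#' @return List with \code{model}, \code{log}, \code{valDSC} and the
#'   \code{data} used.
#' @export
standardSmallRun <- function(seed = 1L, useLRSAR = TRUE, epochs = 12L,
                             baseChannels = 8L, lr = 1e-3, batchSize = 4L,
                             data = NULL, verbose = FALSE) {
  if (is.null(data)) data <- phantomTrainingSet(seed = seed)
  net <- esaUNet(inputSide = 64L, baseChannels = baseChannels,
                 useLRSAR = useLRSAR, seed = .subSeed(seed, 5L))
  fit <- trainESAUNet(net, data$train$images, data$train$masks,
                      valImages = data$val$images,
                      valMasks = data$val$masks,
                      epochs = epochs, lr = lr, batchSize = batchSize,
                      seed = seed, verbose = verbose)
  list(model = fit$model, log = fit$log,
       valDSC = fit$log$valDSC[nrow(fit$log)], data = data)
}
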