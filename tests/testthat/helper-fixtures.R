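# Shared fixtures and independent oracles.

# A small, fast phantom: 64 px, 8 frames, structures scaled down.
smallPhantomSpec <- function(seed = 1L, noiseSigma = 0.05,
                             pulsationAmplitude = 0.2, nFrames = 8L) {
  phantomSpec(imageSide = 64L, nFrames = nFrames,
              chamberCenters = rbind(right_atrium = c(40, 40),
                                     left_atrium = c(30, 18)),
              chamberBaseRadii = c(9, 7),
              pulsationAmplitude = pulsationAmplitude,
              aortaCenter = c(16, 46), aortaRadius = 6,
              noiseSigma = noiseSigma, seed = seed)
}

# Rasterize the rim of a circle into a logical matrix.
rasterizeCircle <- function(h, w, center, r, n = max(64, ceiling(8 * r))) {
  m <- matrix(FALSE, h, w)
  th <- 2 * pi * seq_len(n) / n
  rr <- pmin(pmax(round(center[1] + r * cos(th)), 1), h)
  cc <- pmin(pmax(round(center[2] + r * sin(th)), 1), w)
  m[cbind(rr, cc)] <- TRUE
  m
}

# Independent hysteresis oracle: enumerate strong/weak sets, then expand
# the final set by repeated 8-neighbour dilation until a fixed point.
hysteresisOracle <- function(nms, t1, t2) {
  strong <- nms > t1
  weak <- nms > t2 & !strong
  final <- strong
  repeat {
    grown <- final
    h <- nrow(final); w <- ncol(final)
    pad <- matrix(FALSE, h + 2, w + 2)
    pad[2:(h + 1), 2:(w + 1)] <- final
    nb <- matrix(FALSE, h, w)
    for (dr in 0:2) for (dc in 0:2) {
      if (dr == 1 && dc == 1) next
      nb <- nb | pad[dr + seq_len(h), dc + seq_len(w)]
    }
    grown <- final | (weak & nb)
    if (identical(grown, final)) break
    final <- grown
  }
  final
}

# Dense attention oracle: materialize the full outer-product matrix and
# softmax over its flattened entries.
denseAttentionOracle <- function(Q, K) {
  P <- as.vector(outer(Q, K))
  e <- exp(P - max(P))
  matrix(e / sum(e), length(Q), length(K))
}

# Brute-force per-pixel confusion loop.
confusionOracle <- function(pred, ref, numClasses = 4L) {
  out <- matrix(0L, numClasses, 4L,
                dimnames = list(paste0("class", seq_len(numClasses) - 1L),
                                c("tp", "fp", "tn", "fn")))
  for (i in seq_along(pred)) {
    for (k in seq_len(numClasses) - 1L) {
      p <- pred[i] == k
      r <- ref[i] == k
      col <- if (p && r) "tp" else if (p) "fp" else if (r) "fn" else "tn"
      out[k + 1L, col] <- out[k + 1L, col] + 1L
    }
  }
  out
}

# Boundary-noised CRF fixture built from a small phantom frame: the
# ground-truth mask, a corrupted probability map and the guiding image.
crfPhantomFixture <- function(seed, flipRate = 0.3, confidence = 0.7) {
  sp <- smallPhantomSpec(seed = seed, noiseSigma = 0.02)
  cs <- generatePhantom(sp)
  mk <- masks(cs)[, , 1L]
  img <- frames(cs)[, , 1L]
  probs <- perturbMaskProbs(mk, flipRate = flipRate,
                            confidence = confidence, seed = seed + 500L)
  list(mask = mk, img = img, probs = probs)
}
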