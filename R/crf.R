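#' @include utils.R
NULL

#' Grid CRF configuration
#'
#' Settings for \code{\link{crfRefine}}: a conditional random field over
#' the pixel grid whose unary (state) potentials are the network's log
#' probabilities and whose pairwise (transition) potentials are Potts
#' penalties modulated by local intensity contrast,
#' \code{w * exp(-(dI)^2 / intensityScale^2)} between neighbouring pixels.
#'
#' @param pairwiseWeight Nonnegative Potts weight; 0 reduces refinement to
#'   the per-pixel argmax.
#' @param intensityScale Positive scale of the intensity-difference
#'   modulation, in the image's intensity units.
#' @param nIterations Mean-field iterations (>= 1).
#' @param neighborhood 4 or 8 neighbours.
#' @return Named list of validated settings.
#' @export
crfConfig <- function(pairwiseWeight = 2, intensityScale = 0.5,
                      nIterations = 10L, neighborhood = 8L) {
  if (pairwiseWeight < 0) stop("pairwiseWeight must be >= 0")
  if (intensityScale <= 0) stop("intensityScale must be positive")
  if (nIterations < 1L) stop("nIterations must be >= 1")
  if (!neighborhood %in% c(4L, 8L)) stop("neighborhood must be 4 or 8")
  list(pairwiseWeight = pairwiseWeight, intensityScale = intensityScale,
       nIterations = as.integer(nIterations),
       neighborhood = as.integer(neighborhood))
}

# Neighbour displacement list for a 4- or 8-neighbourhood.
.crfOffsets <- function(neighborhood) {
  o <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (neighborhood == 8L)
    o <- c(o, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  o
}

# Shift a matrix by (dr, dc), zero-filling vacated cells.
.shiftMat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Pairwise contrast weights w_ij for each neighbour offset: the modulated
# Potts strength between pixel (r, c) and its neighbour at (r+dr, c+dc),
# zero where the neighbour falls outside the image.
.crfPairWeights <- function(image, cfg) {
  lapply(.crfOffsets(cfg$neighborhood), function(o) {
    sh <- .shiftMat(image, -o[1L], -o[2L])   # value of the neighbour
    wgt <- cfg$pairwiseWeight *
      exp(-(image - sh)^2 / cfg$intensityScale^2)
    # mask out-of-bounds neighbours
    h <- nrow(image); w <- ncol(image)
    if (o[1L] == 1L) wgt[h, ] <- 0
    if (o[1L] == -1L) wgt[1L, ] <- 0
    if (o[2L] == 1L) wgt[, w] <- 0
    if (o[2L] == -1L) wgt[, 1L] <- 0
    wgt
  })
}

#' Refine a probability map with a grid conditional random field
#'
#' Mean-field inference on a Potts CRF: unary potentials are the negative
#' log network probabilities; each pairwise potential penalizes label
#' disagreement between neighbours, weighted by
#' \code{pairwiseWeight * exp(-(dI)^2 / intensityScale^2)} so boundaries
#' prefer to follow intensity edges. Each of \code{nIterations} sweeps
#' recomputes every pixel's label distribution from its neighbours'
#' current distributions; labels are the final per-pixel argmax.
#' Deterministic; with \code{pairwiseWeight = 0} the result is exactly the
#' argmax of \code{probs}.
#'
#' @param probs H x W x K array of per-pixel class probabilities.
#' @param image H x W intensity image guiding the contrast modulation.
#' @param cfg A \code{\link{crfConfig}}.
#' @return Integer H x W label matrix over 0..K-1.
#' @export
crfRefine <- function(probs, image, cfg = crfConfig()) {
  d <- dim(probs)
  if (!identical(dim(image), d[1:2]))
    stop("image (", paste(dim(image), collapse = "x"),
         ") and probability map (", paste(d[1:2], collapse = "x"),
         ") disagree in size")
  if (cfg$pairwiseWeight == 0)
    return(probsToMask(probs))
  offs <- .crfOffsets(cfg$neighborhood)
  wgts <- .crfPairWeights(image, cfg)
  logU <- log(pmax(probs, 1e-12))
  Q <- probs
  for (it in seq_len(cfg$nIterations)) {
    logQ <- logU
    for (k in seq_len(d[3L])) {
      msg <- matrix(0, d[1L], d[2L])
      for (j in seq_along(offs)) {
        # compatibility reward for agreeing with the neighbour's current
        # belief in class k (Potts: disagreement costs w_ij)
        msg <- msg + wgts[[j]] * .shiftMat(Q[, , k], -offs[[j]][1L],
                                           -offs[[j]][2L])
      }
      logQ[, , k] <- logU[, , k] + msg
    }
    # per-pixel softmax renormalization
    m <- matrix(logQ, d[1L] * d[2L], d[3L])
    m <- m - apply(m, 1L, max)
    e <- exp(m)
    Q <- array(e / rowSums(e), d)
  }
  probsToMask(Q)
}

#' CRF energy of a labelling
#'
#' The (unnormalized) negative log potential of a labelling under the same
#' model \code{\link{crfRefine}} optimizes: unary energy
#' \code{-log P(label)} summed over pixels plus, for each neighbouring
#' pair with unequal labels, the contrast-modulated Potts weight (each
#' pair counted once).
#'
#' @param labels Integer H x W label matrix over 0..K-1.
#' @param probs H x W x K probability array.
#' @param image H x W intensity image.
#' @param cfg A \code{\link{crfConfig}}.
#' @return Single numeric energy (lower is better).
#' @export
crfEnergy <- function(labels, probs, image, cfg = crfConfig()) {
  d <- dim(probs)
  if (!identical(dim(labels), d[1:2]) || !identical(dim(image), d[1:2]))
    stop("labels, image and probability map must share H x W")
  n <- d[1L] * d[2L]
  pm <- matrix(probs, n, d[3L])
  unary <- -sum(log(pmax(pm[cbind(seq_len(n), as.integer(labels) + 1L)],
                         1e-12)))
  # count each pair once: down, right (and the two down-diagonals for 8)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (cfg$neighborhood == 8L)
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  pair <- 0
  h <- d[1L]; w <- d[2L]
  for (o in offs) {
    sh <- .shiftMat(labels + 1L, -o[1L], -o[2L])  # neighbour label + 1
    diffLab <- (labels + 1L) != sh & sh != 0L
    wgt <- cfg$pairwiseWeight * exp(-(image - .shiftMat(image, -o[1L],
                                                        -o[2L]))^2 /
                                    cfg$intensityScale^2)
    valid <- matrix(TRUE, h, w)
    if (o[1L] == 1L) valid[h, ] <- FALSE
    if (o[2L] == 1L) valid[, w] <- FALSE
    if (o[2L] == -1L) valid[, 1L] <- FALSE
    pair <- pair + sum(wgt[diffLab & valid])
  }
  unary + pair
}

#' Simulate a noisy network output from a reference mask
#'
#' Test/benchmark utility: converts a ground-truth mask into a plausible
#' probability map whose boundary pixels are corrupted -- each pixel within
#' one pixel of a class boundary flips to a neighbouring class's label with
#' probability \code{flipRate}, and the map assigns the (possibly flipped)
#' label \code{confidence} probability with the rest spread uniformly.
#' Used to exercise CRF refinement without training a network.
#'
#' @param mask Integer H x W reference mask over 0..K-1.
#' @param numClasses K.
#' @param flipRate Probability a boundary pixel takes a neighbour's label.
#' @param confidence Probability mass on the chosen label.
#' @param seed RNG seed.
#' @return H x W x K probability array.
#' @export
perturbMaskProbs <- function(mask, numClasses = 4L, flipRate = 0.25,
                             confidence = 0.7, seed = 1L) {
  h <- nrow(mask); w <- ncol(mask)
  # boundary = pixels whose 4-neighbourhood holds another label
  bnd <- matrix(FALSE, h, w)
  for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    sh <- .shiftMat(mask + 1L, -o[1L], -o[2L])
    bnd <- bnd | (sh != 0L & sh != mask + 1L)
  }
  noisy <- mask
  .withSeed(seed, {
    flip <- bnd & matrix(stats::runif(h * w) < flipRate, h, w)
    idx <- which(flip)
    if (length(idx)) {
      # adopt the label of a random 4-neighbour
      for (i in idx) {
        r <- ((i - 1L) %% h) + 1L
        cl <- ((i - 1L) %/% h) + 1L
        nb <- list(c(r - 1L, cl), c(r + 1L, cl), c(r, cl - 1L),
                   c(r, cl + 1L))
        nb <- nb[vapply(nb, function(p)
          p[1L] >= 1L && p[1L] <= h && p[2L] >= 1L && p[2L] <= w,
          logical(1))]
        pick <- nb[[sample.int(length(nb), 1L)]]
        noisy[i] <- mask[pick[1L], pick[2L]]
      }
    }
  })
  probs <- array((1 - confidence) / (numClasses - 1L),
                 c(h, w, numClasses))
  for (k in seq_len(numClasses) - 1L) {
    sel <- noisy == k
    pk <- probs[, , k + 1L]
    pk[sel] <- confidence
    probs[, , k + 1L] <- pk
  }
  probs
}
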