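#' @include AllClasses.R
NULL

#' Per-pixel temporal standard deviation of a cine sequence
#'
#' The first stage of ROI detection: a standard-deviation filter over the
#' time axis. Pixels whose intensity varies strongly over the cardiac cycle
#' (chamber rims swept by the pulsating wall) light up; static tissue and
#' background stay at the noise floor. The population form (divide by T) is
#' used, so a pixel alternating 0,1 over an even number of frames scores
#' exactly 0.5.
#'
#' @param x A \linkS4class{CineSequence} or an H x W x T numeric array.
#' @return Numeric H x W matrix of per-pixel standard deviations.
#' @export
#' @examples
#' a <- array(rep(c(0, 1), each = 4), c(2, 2, 2))
#' temporalStdDev(a)   # all 0.5
temporalStdDev <- function(x) {
  fr <- if (methods::is(x, "CineSequence")) frames(x) else x
  if (length(dim(fr)) != 3L)
    stop("expected an H x W x T array")
  if (dim(fr)[3L] < 2L)
    stop("temporal standard deviation needs at least 2 frames")
  mu <- rowMeans(fr, dims = 2L)
  v <- rowMeans(fr * fr, dims = 2L) - mu * mu
  sqrt(pmax(v, 0))
}

#' Gaussian smoothing with reflected borders
#'
#' Separable Gaussian convolution (kernel truncated at 3 sigma and
#' renormalized to unit sum), the first Canny step. Linear and
#' shift-invariant; constant images are preserved exactly because borders
#' are reflect-padded.
#'
#' @param img Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; must be positive.
#' @return Smoothed matrix of the same size.
#' @export
gaussianSmooth <- function(img, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number")
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-(seq(-k, k))^2 / (2 * sigma^2))
  g <- g / sum(g)
  p <- .padReflect(img, k)
  h <- nrow(img); w <- ncol(img)
  # rows pass
  acc <- matrix(0, h, w + 2L * k)
  for (i in seq_along(g))
    acc <- acc + g[i] * p[i:(i + h - 1L), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(g))
    out <- out + g[i] * acc[, i:(i + w - 1L), drop = FALSE]
  out
}

#' The Sobel convolution kernels
#'
#' The 3 x 3 arrays used to estimate horizontal and vertical gradients.
#' \code{Sx} responds to intensity change along columns (x), \code{Sy}
#' along rows (y).
#'
#' @return List with matrices \code{Sx} and \code{Sy}.
#' @export
sobelKernels <- function() {
  list(
    Sx = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE),
    Sy = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
  )
}

# Correlate a matrix with a 3x3 kernel, reflect-padded borders.
.filter3 <- function(img, k3) {
  h <- nrow(img); w <- ncol(img)
  p <- .padReflect(img, 1L)
  out <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2) {
    kk <- k3[dr + 1L, dc + 1L]
    if (kk != 0)
      out <- out + kk * p[dr + seq_len(h), dc + seq_len(w), drop = FALSE]
  }
  out
}

#' Sobel gradient field with eight-way quantized directions
#'
#' Second Canny step: gradients Gx, Gy by convolution with the Sobel
#' kernels, magnitude sqrt(Gx^2 + Gy^2), and gradient direction quantized
#' to the eight compass angles. The conventional direction
#' \code{atan2(Gy, Gx)} is the default; \code{direction = "printed"}
#' computes \code{atan2(Gx, Gy)} instead (the transposed variant some
#' texts print).
#'
#' @param img Numeric matrix, at least 3 x 3.
#' @param direction Either \code{"conventional"} (default) or
#'   \code{"printed"}; see Details.
#' @return A \linkS4class{GradientField}.
#' @export
sobelGradients <- function(img, direction = c("conventional", "printed")) {
  direction <- match.arg(direction)
  if (nrow(img) < 3L || ncol(img) < 3L)
    stop("image must be at least 3 x 3 for the Sobel kernels")
  k <- sobelKernels()
  gx <- .filter3(img, k$Sx)
  gy <- .filter3(img, k$Sy)
  mag <- sqrt(gx^2 + gy^2)
  th <- if (direction == "conventional") atan2(gy, gx) else atan2(gx, gy)
  deg <- (th * 180 / pi) %% 360
  quant <- (round(deg / 45) %% 8) * 45
  new("GradientField", gx = gx, gy = gy, magnitude = mag,
      direction = quant)
}

# (drow, dcol) step for each quantized direction, in degrees.
.dirStep <- function(deg) {
  switch(as.character(deg %% 180),
         "0" = c(0L, 1L),     # horizontal gradient: compare left/right
         "45" = c(-1L, 1L),
         "90" = c(-1L, 0L),   # vertical gradient: compare up/down
         "135" = c(-1L, -1L))
}

#' Non-maximum suppression along the gradient direction
#'
#' Third Canny step: a pixel survives only if its gradient magnitude is at
#' least that of both neighbours along its quantized gradient direction
#' (opposite directions compare the same neighbour pair). Survivors keep
#' their magnitude; all other pixels are set to zero, thinning thick
#' boundary responses to single-pixel ridges.
#'
#' @param g A \linkS4class{GradientField}.
#' @return Numeric matrix of suppressed magnitudes.
#' @export
nonMaxSuppression <- function(g) {
  stopifnot(methods::is(g, "GradientField"))
  mag <- g@magnitude
  h <- nrow(mag); w <- ncol(mag)
  p <- .padZero(mag, 1L)
  keep <- matrix(FALSE, h, w)
  for (deg in c(0, 45, 90, 135)) {
    sel <- (g@direction %% 180) == deg
    if (!any(sel)) next
    st <- .dirStep(deg)
    fwd <- p[1L + st[1L] + seq_len(h), 1L + st[2L] + seq_len(w)]
    bwd <- p[1L - st[1L] + seq_len(h), 1L - st[2L] + seq_len(w)]
    keep[sel] <- mag[sel] >= fwd[sel] & mag[sel] >= bwd[sel]
  }
  out <- mag
  out[!keep] <- 0
  out
}

#' Otsu threshold of the positive responses of a magnitude map
#'
#' Maximizes between-class variance over a 256-bin histogram of the
#' strictly positive values. Used to pick the upper hysteresis threshold
#' when none is given.
#'
#' @param x Numeric matrix or vector of nonnegative responses.
#' @param nbins Histogram resolution.
#' @return A single threshold on the scale of \code{x}.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  v <- x[x > 0]
  if (!length(v)) return(0)
  if (min(v) == max(v)) return(min(v) / 2)
  br <- seq(min(v), max(v), length.out = nbins + 1L)
  hc <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- hc / sum(hc)
  mid <- (br[-1L] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mid)
  muT <- mu[length(mu)]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mid[which.max(sb)]
}

#' Double-threshold hysteresis edge linking
#'
#' Fourth Canny step: responses above \code{t1} are strong edges, those in
#' \code{(t2, t1]} weak; the final map keeps strong pixels plus every weak
#' pixel connected (8-connectivity, transitively) to a strong one. The
#' default lower threshold follows the conventional 2:1 ratio,
#' \code{t2 = t1 / 2}.
#'
#' @param nms Numeric matrix of suppressed gradient magnitudes.
#' @param t1 Upper threshold; must exceed \code{t2}.
#' @param t2 Lower threshold; defaults to \code{t1 / 2}.
#' @return An \linkS4class{EdgeMap}.
#' @export
hysteresisThreshold <- function(nms, t1, t2 = t1 / 2) {
  if (!(t1 > t2) || t2 < 0)
    stop("thresholds must satisfy t1 > t2 >= 0")
  strong <- nms > t1
  weak <- nms > t2 & !strong
  final <- strong
  h <- nrow(nms); w <- ncol(nms)
  # BFS flood fill from strong pixels across the weak set, 8-connected
  seeds <- which(strong)
  queue <- integer(h * w)
  qn <- length(seeds)
  if (qn) queue[seq_len(qn)] <- seeds
  qi <- 1L
  cand <- strong | weak
  visited <- strong
  off <- as.integer(c(-1, 1, -h, h, -h - 1, -h + 1, h - 1, h + 1))
  n <- h * w
  while (qi <= qn) {
    idx <- queue[qi]; qi <- qi + 1L
    r <- ((idx - 1L) %% h) + 1L
    for (o in off) {
      j <- idx + o
      if (j < 1L || j > n) next
      rj <- ((j - 1L) %% h) + 1L
      if (abs(rj - r) > 1L) next  # wrapped across a column edge
      if (cand[j] && !visited[j]) {
        visited[j] <- TRUE
        final[j] <- TRUE
        qn <- qn + 1L
        queue[qn] <- j
      }
    }
  }
  new("EdgeMap", strong = strong, weak = weak, final = final,
      t1 = t1, t2 = t2)
}

#' Full Canny edge-detection chain
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' double-threshold hysteresis in sequence. With \code{t1 = NULL} the upper
#' threshold is chosen by Otsu's method on the suppressed magnitudes and
#' the lower one follows the 2:1 ratio.
#'
#' @param img Numeric matrix.
#' @param sigma Gaussian smoothing width in pixels.
#' @param t1,t2 Hysteresis thresholds; \code{NULL} picks them automatically.
#' @param direction Gradient-direction convention, see
#'   \code{\link{sobelGradients}}.
#' @return An \linkS4class{EdgeMap}.
#' @export
cannyEdges <- function(img, sigma = 1, t1 = NULL, t2 = NULL,
                       direction = "conventional") {
  sm <- gaussianSmooth(img, sigma)
  g <- sobelGradients(sm, direction)
  nms <- nonMaxSuppression(g)
  if (is.null(t1)) t1 <- otsuThreshold(nms)
  if (is.null(t2)) t2 <- t1 / 2
  hysteresisThreshold(nms, t1, t2)
}
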