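#' @include hough.R
NULL

#' ROI detection configuration
#'
#' Tunables for \code{\link{detectROI}}: smoothing width, hysteresis
#' thresholds (\code{NULL} means Otsu with the 2:1 ratio), the aortic
#' radius search range in pixels, the minimum fraction of a circle's
#' circumference that must be supported by accumulator votes, and the crop
#' side.
#'
#' @param sigma Gaussian smoothing width in pixels.
#' @param t1,t2 Hysteresis thresholds or \code{NULL} for automatic choice.
#' @param rMin,rMax Aortic radius range in pixels (defaults 8-25).
#' @param minVoteFrac Minimum supported circumference fraction for a circle
#'   to count as found (0.25 = a quarter of the circle's rim).
#' @param minSignalRatio Minimum ratio of the 99.9th percentile to the
#'   median of the temporal std-dev map; below it the sequence carries no
#'   cardiac motion signal and detection aborts.
#' @param cropSide Side of the square crop window (128).
#' @param direction Gradient-direction convention for the Canny stage.
#' @return Named list of validated settings.
#' @export
roiConfig <- function(sigma = 1.5, t1 = NULL, t2 = NULL,
                      rMin = 8, rMax = 25, minVoteFrac = 0.25,
                      minSignalRatio = 2, cropSide = 128L,
                      direction = "conventional") {
  if (!(rMin < rMax)) stop("rMin must be below rMax")
  if (sigma <= 0) stop("sigma must be positive")
  if (minVoteFrac < 0 || minVoteFrac > 1)
    stop("minVoteFrac must lie in [0, 1]")
  list(sigma = sigma, t1 = t1, t2 = t2, rMin = rMin, rMax = rMax,
       minVoteFrac = minVoteFrac, minSignalRatio = minSignalRatio,
       cropSide = as.integer(cropSide), direction = direction)
}

# Mean of map values strictly inside a circle.
.meanInsideCircle <- function(map, center, radius) {
  h <- nrow(map); w <- ncol(map)
  r0 <- max(1L, floor(center[1L] - radius))
  r1 <- min(h, ceiling(center[1L] + radius))
  c0 <- max(1L, floor(center[2L] - radius))
  c1 <- min(w, ceiling(center[2L] + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1L])^2, (cc - center[2L])^2, `+`)
  sub <- map[rr, cc, drop = FALSE]
  mean(sub[d2 <= radius^2])
}

#' Detect the cardiac region of interest and its aortic centre
#'
#' Runs the full ROI chain on a cine sequence. The temporal
#' standard-deviation map localizes the moving cardiac region and supplies
#' the evidence that a structure is near-static; the Canny chain (Gaussian
#' smoothing, Sobel gradients, non-maximum suppression, double-threshold
#' hysteresis) runs on the temporal-mean image, where the aorta appears as
#' a circular rim, and a Hough circle transform proposes circles. Among
#' candidates whose radius lies in the configured aortic range and whose
#' circumference support passes \code{minVoteFrac}, the circle with the
#' lowest mean interior temporal standard deviation is selected -- the
#' most static circular structure, i.e. the aorta. A square crop window
#' (128 x 128 by default) is centred on it, clamped to image bounds.
#'
#' @param seq A \linkS4class{CineSequence}.
#' @param config Settings from \code{\link{roiConfig}}.
#' @return An \linkS4class{ROIResult}.
#' @seealso \code{\link{cropAndNormalize}} to apply the window.
#' @export
detectROI <- function(seq, config = roiConfig()) {
  sd_map <- temporalStdDev(seq)
  sig <- stats::quantile(sd_map, 0.999) / max(stats::median(sd_map),
                                              .Machine$double.eps)
  if (sig < config$minSignalRatio)
    stop("ROI not found: temporal std-dev map shows no cardiac motion ",
         "signal (peak/median ratio ", round(sig, 2), " < ",
         config$minSignalRatio, ")")
  meanImg <- rowMeans(frames(seq), dims = 2L)
  em <- cannyEdges(meanImg, sigma = config$sigma, t1 = config$t1,
                   t2 = config$t2, direction = config$direction)
  cands <- houghCircles(em, config$rMin, config$rMax, nCandidates = 12L)
  cands <- cands[cands$voteFrac >= config$minVoteFrac, , drop = FALSE]
  if (!nrow(cands))
    stop("ROI not found: no circle candidate in radius range [",
         config$rMin, ", ", config$rMax, "] with circumference support >= ",
         config$minVoteFrac)
  inner <- vapply(seq_len(nrow(cands)), function(i)
    .meanInsideCircle(sd_map, c(cands$row[i], cands$col[i]),
                      max(1, cands$r[i] - 1)), numeric(1))
  best <- cands[which.min(inner), ]
  d <- dim(sd_map)
  side <- config$cropSide
  if (d[1L] < side || d[2L] < side)
    stop("image (", d[1L], " x ", d[2L], ") is smaller than the ",
         side, " x ", side, " crop window")
  org <- vapply(1:2, function(k)
    min(max(1L, as.integer(round(best[[k]] - side / 2))), d[k] - side + 1L),
    integer(1))
  new("ROIResult", center = c(best$row, best$col), radius = best$r,
      cropOrigin = org, cropSide = side, stddevMap = sd_map,
      votes = best$votes)
}

#' Crop a sequence to the ROI window and z-score its intensities
#'
#' Frames and masks are cropped identically to the window carried by the
#' ROI result; intensities are then standardized per sequence to zero mean
#' and unit standard deviation, the normalization the segmentation network
#' expects. Mask labels are untouched.
#'
#' @param seq A \linkS4class{CineSequence}.
#' @param roi An \linkS4class{ROIResult} whose window lies within
#'   \code{seq}.
#' @return A cropped, normalized \linkS4class{CineSequence}.
#' @export
cropAndNormalize <- function(seq, roi) {
  d <- dim(seq)
  o <- cropOrigin(roi)
  side <- roi@cropSide
  if (any(o < 1L) || o[1L] + side - 1L > d[1L] || o[2L] + side - 1L > d[2L])
    stop("crop window exceeds image bounds")
  ri <- o[1L]:(o[1L] + side - 1L)
  ci <- o[2L]:(o[2L] + side - 1L)
  fr <- frames(seq)[ri, ci, , drop = FALSE]
  mu <- mean(fr)
  sdv <- stats::sd(as.vector(fr))
  if (sdv == 0) sdv <- 1
  fr <- (fr - mu) / sdv
  mk <- if (length(masks(seq))) masks(seq)[ri, ci, , drop = FALSE] else NULL
  CineSequence(fr, mk, pixelSpacing = pixelSpacing(seq))
}
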