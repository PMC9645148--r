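#' @import methods
NULL

#' Class labels used throughout the package
#'
#' Segmentation masks are integer arrays over four classes: 0 = background,
#' 1 = right atrium, 2 = left atrium, 3 = aorta.
#'
#' @return Named integer vector mapping structure names to label codes.
#' @export
#' @examples
#' cineClassLabels()
cineClassLabels <- function() {
  c(background = 0L, right_atrium = 1L, left_atrium = 2L, aorta = 3L)
}

#' PhantomSpec: geometry and acquisition parameters of a synthetic cine study
#'
#' Describes one synthetic short-axis beating-heart phantom: two pulsating
#' near-circular chambers (right and left atrium), one near-static circular
#' aorta, and additive Gaussian intensity noise. Sequences emulate clinical
#' cine acquisitions of 28 to 40 frames per cardiac cycle at roughly 235-263
#' pixels per side.
#'
#' @slot imageSide integer, image side length in pixels.
#' @slot nFrames integer, frames per cardiac cycle.
#' @slot chamberCenters 2x2 numeric matrix, (row, col) centres of the right
#'   and left atrium in pixels.
#' @slot chamberBaseRadii numeric length 2, base radii in pixels.
#' @slot pulsationAmplitude numeric in [0, 1), fractional radial excursion of
#'   the chambers over the cycle.
#' @slot aortaCenter numeric length 2, (row, col) of the aorta centre.
#' @slot aortaRadius numeric, aorta radius in pixels (constant over time).
#' @slot noiseSigma numeric >= 0, standard deviation of additive Gaussian
#'   noise in intensity units.
#' @slot seed integer, RNG seed; a fixed seed gives byte-identical output.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    imageSide = "integer",
    nFrames = "integer",
    chamberCenters = "matrix",
    chamberBaseRadii = "numeric",
    pulsationAmplitude = "numeric",
    aortaCenter = "numeric",
    aortaRadius = "numeric",
    noiseSigma = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  s <- object@imageSide
  if (length(s) != 1L || is.na(s) || s < 32L)
    msg <- c(msg, "imageSide must be a single integer >= 32")
  if (length(object@nFrames) != 1L || object@nFrames < 2L)
    msg <- c(msg, "nFrames must be a single integer >= 2")
  if (!is.numeric(object@chamberCenters) || ncol(object@chamberCenters) != 2L)
    msg <- c(msg, "chamberCenters must be an n x 2 (row, col) matrix")
  if (nrow(object@chamberCenters) != length(object@chamberBaseRadii))
    msg <- c(msg, "one base radius per chamber centre is required")
  amp <- object@pulsationAmplitude
  if (length(amp) != 1L || amp < 0 || amp >= 1)
    msg <- c(msg, "pulsationAmplitude must lie in [0, 1)")
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg) == 0L) {
    # every structure must stay inside the frame at maximal pulsation
    maxr <- object@chamberBaseRadii * (1 + amp)
    ctr <- rbind(object@chamberCenters, object@aortaCenter)
    rad <- c(maxr, object@aortaRadius)
    nm <- c(rownames(object@chamberCenters), "aorta")
    if (is.null(nm) || length(nm) != length(rad))
      nm <- c(paste0("chamber", seq_along(maxr)), "aorta")
    for (k in seq_along(rad)) {
      if (ctr[k, 1L] - rad[k] < 1 || ctr[k, 1L] + rad[k] > s ||
          ctr[k, 2L] - rad[k] < 1 || ctr[k, 2L] + rad[k] > s)
        msg <- c(msg, sprintf(
          "structure '%s' exits the %dx%d frame at maximal pulsation", nm[k], s, s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' CineSequence: one cine study as an intensity stack plus label masks
#'
#' Holds an H x W x T intensity array (arbitrary units) and, when available,
#' an H x W x T integer label array over the classes of
#' \code{\link{cineClassLabels}}. Frames and masks always share dimensions.
#'
#' @slot frames numeric H x W x T array.
#' @slot masks integer H x W x T array (may be of length zero when the study
#'   is unlabelled).
#' @slot pixelSpacing numeric, in-plane pixel spacing in mm (metadata only).
#' @exportClass CineSequence
setClass("CineSequence",
  representation(
    frames = "array",
    masks = "array",
    pixelSpacing = "numeric"
  )
)

setValidity("CineSequence", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3-d (H x W x T) array")
  if (length(object@masks) > 0L) {
    if (!identical(dim(object@frames), dim(object@masks)))
      msg <- c(msg, "frames and masks must share H, W and T")
    lab <- unique(as.integer(object@masks))
    bad <- setdiff(lab, unname(cineClassLabels()))
    if (length(bad))
      msg <- c(msg, sprintf("masks contain undeclared class labels: %s",
                            paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' GradientField: Sobel gradients with quantized directions
#'
#' Per-pixel horizontal and vertical Sobel responses, the gradient magnitude
#' sqrt(gx^2 + gy^2), and the gradient direction quantized to the eight
#' compass angles 0, 45, ..., 315 degrees.
#'
#' @slot gx,gy numeric H x W arrays (intensity per pixel).
#' @slot magnitude numeric H x W array, nonnegative.
#' @slot direction numeric H x W array over {0,45,90,135,180,225,270,315}.
#' @exportClass GradientField
setClass("GradientField",
  representation(gx = "matrix", gy = "matrix",
                 magnitude = "matrix", direction = "matrix")
)

setValidity("GradientField", function(object) {
  msg <- character()
  d <- dim(object@gx)
  if (!identical(d, dim(object@gy)) || !identical(d, dim(object@magnitude)) ||
      !identical(d, dim(object@direction)))
    msg <- c(msg, "gx, gy, magnitude and direction must share dimensions")
  if (any(object@magnitude < -1e-12))
    msg <- c(msg, "magnitude must be nonnegative")
  if (!all(object@direction %in% seq(0, 315, by = 45)))
    msg <- c(msg, "direction must be quantized to {0,45,...,315} degrees")
  if (length(msg)) msg else TRUE
})

#' EdgeMap: double-threshold edge classification with hysteresis
#'
#' Strong edges exceed the upper threshold t1, weak edges lie in (t2, t1];
#' the final map keeps every strong pixel plus each weak pixel 8-connected
#' (possibly transitively) to a strong one. The conventional threshold ratio
#' t1 : t2 = 2 : 1 is the default.
#'
#' @slot strong,weak,final logical H x W matrices.
#' @slot t1,t2 numeric thresholds, t1 > t2.
#' @exportClass EdgeMap
setClass("EdgeMap",
  representation(strong = "matrix", weak = "matrix", final = "matrix",
                 t1 = "numeric", t2 = "numeric")
)

setValidity("EdgeMap", function(object) {
  msg <- character()
  if (any(object@strong & object@weak))
    msg <- c(msg, "a pixel cannot be both strong and weak")
  if (any(object@strong & !object@final))
    msg <- c(msg, "final must contain every strong pixel")
  if (object@t1 <= object@t2)
    msg <- c(msg, "t1 must exceed t2")
  if (length(msg)) msg else TRUE
})

#' ROIResult: detected aortic circle and the 128 x 128 crop window
#'
#' @slot center numeric length 2, detected (row, col) centre in pixels.
#' @slot radius numeric, detected circle radius in pixels.
#' @slot cropOrigin integer length 2, (row, col) of the top-left pixel of
#'   the crop window (1-based, as R arrays are indexed; the window spans
#'   rows cropOrigin[1] .. cropOrigin[1] + cropSide - 1).
#' @slot cropSide integer, crop side length (128 by default).
#' @slot stddevMap numeric H x W matrix, the temporal standard-deviation map.
#' @slot votes numeric, Hough accumulator support for the chosen circle.
#' @exportClass ROIResult
setClass("ROIResult",
  representation(center = "numeric", radius = "numeric",
                 cropOrigin = "integer", cropSide = "integer",
                 stddevMap = "matrix", votes = "numeric")
)

setValidity("ROIResult", function(object) {
  msg <- character()
  side <- object@cropSide
  d <- dim(object@stddevMap)
  o <- object@cropOrigin
  if (any(o < 1L) || o[1L] + side - 1L > d[1L] || o[2L] + side - 1L > d[2L])
    msg <- c(msg, "crop window must lie within image bounds")
  ctr <- object@center
  if (ctr[1L] < o[1L] || ctr[1L] > o[1L] + side - 1L ||
      ctr[2L] < o[2L] || ctr[2L] > o[2L] + side - 1L)
    msg <- c(msg, "detected centre must lie inside the crop window")
  if (length(msg)) msg else TRUE
})
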