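#' @include AllClasses.R
NULL

#' Accessors for CineSequence
#'
#' @param x A \linkS4class{CineSequence}.
#' @return \code{frames} returns the H x W x T intensity array, \code{masks}
#'   the integer label array (zero-length array when unlabelled),
#'   \code{pixelSpacing} the in-plane spacing in mm, \code{nFrames} the
#'   number of frames T.
#' @aliases frames masks pixelSpacing nFrames
#' @name cine-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname cine-accessors
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname cine-accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname cine-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname cine-accessors
setMethod("frames", "CineSequence", function(x) x@frames)

#' @rdname cine-accessors
setMethod("masks", "CineSequence", function(x) x@masks)

#' @rdname cine-accessors
setMethod("pixelSpacing", "CineSequence", function(x) x@pixelSpacing)

#' @rdname cine-accessors
setMethod("nFrames", "CineSequence", function(x) dim(x@frames)[3L])

#' @describeIn cine-accessors dimensions of the intensity stack (H, W, T).
#' @export
setMethod("dim", "CineSequence", function(x) dim(x@frames))

setMethod("show", "CineSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("CineSequence: %d x %d pixels, %d frames%s\n",
              d[1L], d[2L], d[3L],
              if (length(object@masks)) ", with label masks" else ""))
  if (length(object@masks)) {
    lab <- sort(unique(as.integer(object@masks)))
    cat("  labels present:", paste(lab, collapse = " "), "\n")
  }
  cat(sprintf("  intensity range [%.3g, %.3g], pixel spacing %.3g mm\n",
              min(object@frames), max(object@frames), object@pixelSpacing))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d pixels, %d frames/cycle, seed %d\n",
              object@imageSide, object@imageSide, object@nFrames, object@seed))
  cat(sprintf("  chambers: %d, pulsation amplitude %.2f; aorta r = %.1f px; noise sigma %.3g\n",
              nrow(object@chamberCenters), object@pulsationAmplitude,
              object@aortaRadius, object@noiseSigma))
})

setMethod("show", "ROIResult", function(object) {
  cat(sprintf("ROIResult: centre (%.1f, %.1f), radius %.1f px, %g votes\n",
              object@center[1L], object@center[2L], object@radius,
              object@votes))
  cat(sprintf("  crop window: %d x %d at origin (%d, %d)\n",
              object@cropSide, object@cropSide,
              object@cropOrigin[1L], object@cropOrigin[2L]))
})

setMethod("show", "EdgeMap", function(object) {
  cat(sprintf("EdgeMap: %d strong, %d weak, %d final edge pixels (t1 = %.4g, t2 = %.4g)\n",
              sum(object@strong), sum(object@weak), sum(object@final),
              object@t1, object@t2))
})

setMethod("show", "GradientField", function(object) {
  d <- dim(object@gx)
  cat(sprintf("GradientField: %d x %d, max |G| = %.4g\n",
              d[1L], d[2L], max(object@magnitude)))
})

#' Accessors for ROIResult
#'
#' @param x An \linkS4class{ROIResult}.
#' @return \code{roiCenter} the detected (row, col) centre, \code{roiRadius}
#'   the circle radius in pixels, \code{cropOrigin} the 1-based (row, col) of
#'   the crop window's top-left pixel, \code{stddevMap} the temporal
#'   standard-deviation map the detector worked from.
#' @aliases roiCenter roiRadius cropOrigin stddevMap
#' @name roi-accessors
#' @export
setGeneric("roiCenter", function(x) standardGeneric("roiCenter"))

#' @rdname roi-accessors
#' @export
setGeneric("roiRadius", function(x) standardGeneric("roiRadius"))

#' @rdname roi-accessors
#' @export
setGeneric("cropOrigin", function(x) standardGeneric("cropOrigin"))

#' @rdname roi-accessors
#' @export
setGeneric("stddevMap", function(x) standardGeneric("stddevMap"))

#' @rdname roi-accessors
setMethod("roiCenter", "ROIResult", function(x) x@center)

#' @rdname roi-accessors
setMethod("roiRadius", "ROIResult", function(x) x@radius)

#' @rdname roi-accessors
setMethod("cropOrigin", "ROIResult", function(x) x@cropOrigin)

#' @rdname roi-accessors
setMethod("stddevMap", "ROIResult", function(x) x@stddevMap)

#' Accessors for EdgeMap
#'
#' @param x An \linkS4class{EdgeMap}.
#' @return Logical H x W matrices: \code{edgeStrong} the strong set,
#'   \code{edgeWeak} the weak set, \code{edgeFinal} the hysteresis result.
#' @aliases edgeStrong edgeWeak edgeFinal
#' @name edge-accessors
#' @export
setGeneric("edgeStrong", function(x) standardGeneric("edgeStrong"))

#' @rdname edge-accessors
#' @export
setGeneric("edgeWeak", function(x) standardGeneric("edgeWeak"))

#' @rdname edge-accessors
#' @export
setGeneric("edgeFinal", function(x) standardGeneric("edgeFinal"))

#' @rdname edge-accessors
setMethod("edgeStrong", "EdgeMap", function(x) x@strong)

#' @rdname edge-accessors
setMethod("edgeWeak", "EdgeMap", function(x) x@weak)

#' @rdname edge-accessors
setMethod("edgeFinal", "EdgeMap", function(x) x@final)

#' Construct a CineSequence
#'
#' @param frames Numeric H x W x T array of intensities.
#' @param masks Optional integer H x W x T array of class labels
#'   (see \code{\link{cineClassLabels}}).
#' @param pixelSpacing In-plane pixel spacing in mm.
#' @return A validated \linkS4class{CineSequence}.
#' @export
#' @examples
#' cs <- CineSequence(array(0, c(8, 8, 4)))
#' dim(cs)
CineSequence <- function(frames, masks = NULL, pixelSpacing = 1.0) {
  if (is.null(masks)) masks <- array(integer(0), c(0L, 0L, 0L))
  storage.mode(masks) <- "integer"
  new("CineSequence", frames = frames, masks = masks,
      pixelSpacing = pixelSpacing)
}
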