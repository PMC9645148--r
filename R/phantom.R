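#' @include AllClasses.R
NULL

# Noise-free tissue intensities (arbitrary units). Background is dark; each
# structure gets its own plateau so the classes are radiometrically distinct.
.phantomIntensity <- c(background = 0.2, right_atrium = 0.5,
                       left_atrium = 0.7, aorta = 0.9)

#' Specify a synthetic beating-heart cine phantom
#'
#' Builds a \linkS4class{PhantomSpec}. When \code{imageSide} or
#' \code{nFrames} are left \code{NULL} they are drawn (using \code{seed})
#' from the ranges typical of clinical short-axis cine studies: 235-263
#' pixels per side and 28-40 frames per cardiac cycle. Structure geometry
#' defaults scale with the image side: two pulsating atria placed
#' mid-image and a smaller static aorta above and between them.
#'
#' @param imageSide Image side length in pixels, or \code{NULL} to sample
#'   from 235-263.
#' @param nFrames Frames per cardiac cycle, or \code{NULL} to sample from
#'   28-40.
#' @param chamberCenters 2 x 2 matrix of (row, col) chamber centres, or
#'   \code{NULL} for defaults proportional to \code{imageSide}.
#' @param chamberBaseRadii Numeric length 2 base radii in pixels, or
#'   \code{NULL} for defaults.
#' @param pulsationAmplitude Fractional radial excursion of the chambers in
#'   [0, 1); default 0.2.
#' @param aortaCenter (row, col) of the aorta, or \code{NULL} for default.
#' @param aortaRadius Aorta radius in pixels; default 12.
#' @param noiseSigma Additive Gaussian noise standard deviation in intensity
#'   units; default 0.05 (foreground/background contrast is >= 0.3).
#' @param seed Integer RNG seed.
#' @return A validated \linkS4class{PhantomSpec}.
#' @export
#' @examples
#' spec <- phantomSpec(seed = 7)
#' spec
phantomSpec <- function(imageSide = NULL, nFrames = NULL,
                        chamberCenters = NULL, chamberBaseRadii = NULL,
                        pulsationAmplitude = 0.2,
                        aortaCenter = NULL, aortaRadius = 12,
                        noiseSigma = 0.05, seed = 1L) {
  draw <- is.null(imageSide) || is.null(nFrames)
  if (draw) {
    rng <- .withSeed(seed + 1000003L, {
      list(side = sample(235:263, 1L), nt = sample(28:40, 1L))
    })
    if (is.null(imageSide)) imageSide <- rng$side
    if (is.null(nFrames)) nFrames <- rng$nt
  }
  s <- as.integer(imageSide)
  if (is.null(chamberCenters)) {
    chamberCenters <- rbind(
      right_atrium = c(0.60, 0.62) * s,
      left_atrium = c(0.50, 0.34) * s
    )
  }
  if (is.null(chamberBaseRadii))
    chamberBaseRadii <- c(0.12, 0.10) * s
  if (is.null(aortaCenter))
    aortaCenter <- c(0.34, 0.55) * s
  new("PhantomSpec",
      imageSide = s, nFrames = as.integer(nFrames),
      chamberCenters = chamberCenters,
      chamberBaseRadii = chamberBaseRadii,
      pulsationAmplitude = pulsationAmplitude,
      aortaCenter = as.numeric(aortaCenter),
      aortaRadius = as.numeric(aortaRadius),
      noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Radius of each phantom structure at a given frame
#'
#' Chamber radii vary sinusoidally over one full cycle (systole/diastole);
#' the aorta radius is constant. Frame 1 is at the mean radius.
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @param t Frame index (1-based, may be a vector).
#' @return Matrix with one row per frame and columns
#'   \code{right_atrium}, \code{left_atrium}, \code{aorta}.
#' @export
phantomRadii <- function(spec, t = seq_len(spec@nFrames)) {
  phase <- sin(2 * pi * (t - 1) / spec@nFrames)
  cbind(
    right_atrium = spec@chamberBaseRadii[1L] *
      (1 + spec@pulsationAmplitude * phase),
    left_atrium = spec@chamberBaseRadii[2L] *
      (1 + spec@pulsationAmplitude * phase),
    aorta = rep(spec@aortaRadius, length(t))
  )
}

#' Generate a synthetic cine sequence with ground-truth masks
#'
#' Renders the phantom described by \code{spec}: per frame, each chamber is
#' a filled circle whose radius follows one sinusoidal cycle over the
#' sequence, the aorta is a constant circle, the background is a uniform
#' plateau, and i.i.d. Gaussian noise is added to the intensities (never to
#' the masks). Masks exactly trace the noiseless shapes. A fixed seed gives
#' byte-identical output.
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @return A \linkS4class{CineSequence} with frames and masks.
#' @export
#' @examples
#' seq <- generatePhantom(phantomSpec(imageSide = 64, nFrames = 8,
#'   chamberCenters = rbind(c(40, 40), c(30, 18)),
#'   chamberBaseRadii = c(8, 7), aortaCenter = c(16, 44), aortaRadius = 5,
#'   seed = 1))
#' dim(seq)
generatePhantom <- function(spec) {
  validObject(spec)
  s <- spec@imageSide
  nt <- spec@nFrames
  labs <- cineClassLabels()
  rr <- matrix(seq_len(s), s, s)
  cc <- matrix(seq_len(s), s, s, byrow = TRUE)
  radii <- phantomRadii(spec)
  centers <- rbind(spec@chamberCenters, aorta = spec@aortaCenter)
  # squared distance to each structure centre, shared across frames
  d2 <- lapply(seq_len(nrow(centers)), function(k)
    (rr - centers[k, 1L])^2 + (cc - centers[k, 2L])^2)
  frames <- array(.phantomIntensity[["background"]], c(s, s, nt))
  masks <- array(0L, c(s, s, nt))
  structNames <- c("right_atrium", "left_atrium", "aorta")
  for (t in seq_len(nt)) {
    fr <- frames[, , t]
    mk <- masks[, , t]
    for (k in seq_along(structNames)) {
      inside <- d2[[k]] <= radii[t, structNames[k]]^2
      fr[inside] <- .phantomIntensity[[structNames[k]]]
      mk[inside] <- labs[[structNames[k]]]
    }
    frames[, , t] <- fr
    masks[, , t] <- mk
  }
  if (spec@noiseSigma > 0) {
    noise <- .withSeed(spec@seed,
      array(stats::rnorm(length(frames), sd = spec@noiseSigma), dim(frames)))
    frames <- frames + noise
  }
  CineSequence(frames, masks)
}
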