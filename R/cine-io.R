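#' @include AllGenerics.R
NULL

#' Read and write cine sequences as NIfTI volumes
#'
#' A \linkS4class{CineSequence} is stored as a pair of NIfTI files sharing a
#' prefix: \code{<prefix>_frames.nii.gz} (float intensities, H x W x T) and,
#' when masks are present, \code{<prefix>_masks.nii.gz} (integer labels).
#' The in-plane pixel spacing is carried in the NIfTI pixdim header.
#' Round-tripping preserves frames, masks and spacing to stored (single
#' float) precision.
#'
#' @param seq A \linkS4class{CineSequence}.
#' @param prefix File path prefix; the two file names are derived from it.
#' @return \code{writeCineNIfTI} invisibly returns the written paths;
#'   \code{readCineNIfTI} returns a \linkS4class{CineSequence}.
#' @export
writeCineNIfTI <- function(seq, prefix) {
  validObject(seq)
  paths <- c(frames = paste0(prefix, "_frames.nii.gz"),
             masks = paste0(prefix, "_masks.nii.gz"))
  img <- RNifti::asNifti(frames(seq),
                         pixdim = c(pixelSpacing(seq), pixelSpacing(seq), 1))
  RNifti::writeNifti(img, paths[["frames"]])
  if (length(masks(seq)) > 0L) {
    mk <- RNifti::asNifti(masks(seq), datatype = "int16")
    RNifti::writeNifti(mk, paths[["masks"]])
  } else {
    paths <- paths["frames"]
  }
  invisible(paths)
}

#' @rdname writeCineNIfTI
#' @export
readCineNIfTI <- function(prefix) {
  fpath <- paste0(prefix, "_frames.nii.gz")
  mpath <- paste0(prefix, "_masks.nii.gz")
  if (!file.exists(fpath))
    stop("no cine frames found at '", fpath, "'")
  img <- tryCatch(RNifti::readNifti(fpath), error = function(e)
    stop("malformed NIfTI frames file '", fpath, "': ", conditionMessage(e)))
  fr <- array(as.numeric(img), dim(img))
  if (length(dim(fr)) != 3L)
    stop("malformed cine frames: expected 3 dimensions (H x W x T), got ",
         length(dim(fr)))
  spacing <- RNifti::pixdim(img)[1L]
  mk <- NULL
  if (file.exists(mpath)) {
    mimg <- tryCatch(RNifti::readNifti(mpath), error = function(e)
      stop("malformed NIfTI masks file '", mpath, "': ", conditionMessage(e)))
    mk <- array(as.integer(mimg), dim(mimg))
    if (!identical(dim(mk), dim(fr)))
      stop("masks dimensions ", paste(dim(mk), collapse = "x"),
           " do not match frames ", paste(dim(fr), collapse = "x"))
  }
  CineSequence(fr, mk, pixelSpacing = spacing)
}

#' Read and write cine sequences as ordered PNG frame stacks
#'
#' Alternate on-disk dialect: one 16-bit grayscale PNG per frame
#' (\code{frame_0001.png}, ...) with intensities affinely rescaled to
#' [0, 1] (the scale and offset are recorded in \code{range.json} so the
#' round trip restores original units), plus one 8-bit PNG per mask frame
#' (\code{mask_0001.png}) holding the raw label codes.
#'
#' @param seq A \linkS4class{CineSequence}.
#' @param dir Directory for the stack (created if absent).
#' @return \code{writeCinePNG} invisibly returns \code{dir};
#'   \code{readCinePNG} returns a \linkS4class{CineSequence}.
#' @export
writeCinePNG <- function(seq, dir) {
  validObject(seq)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fr <- frames(seq)
  lo <- min(fr); hi <- max(fr)
  scale <- if (hi > lo) hi - lo else 1
  nt <- dim(fr)[3L]
  for (t in seq_len(nt)) {
    png::writePNG((fr[, , t] - lo) / scale,
                  file.path(dir, sprintf("frame_%04d.png", t)))
    if (length(masks(seq)))
      png::writePNG(masks(seq)[, , t] / 255,
                    file.path(dir, sprintf("mask_%04d.png", t)))
  }
  jsonlite::write_json(
    list(lo = lo, scale = scale, pixelSpacing = pixelSpacing(seq)),
    file.path(dir, "range.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeCinePNG
#' @export
readCinePNG <- function(dir) {
  ff <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                        full.names = TRUE))
  if (!length(ff)) stop("no PNG frames found in '", dir, "'")
  meta <- jsonlite::read_json(file.path(dir, "range.json"))
  fr <- vapply(ff, function(p) png::readPNG(p), png::readPNG(ff[1L]))
  fr <- fr * meta$scale + meta$lo
  mf <- sort(list.files(dir, pattern = "^mask_\\d+\\.png$",
                        full.names = TRUE))
  mk <- NULL
  if (length(mf)) {
    if (length(mf) != length(ff))
      stop("frame/mask count mismatch in '", dir, "'")
    mk <- vapply(mf, function(p) round(png::readPNG(p) * 255),
                 png::readPNG(mf[1L]))
    storage.mode(mk) <- "integer"
  }
  CineSequence(fr, mk, pixelSpacing = meta$pixelSpacing)
}

#' Serialize a PhantomSpec to and from YAML
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @param path YAML file path.
#' @return \code{readPhantomSpec} returns a validated
#'   \linkS4class{PhantomSpec}; \code{writePhantomSpec} invisibly returns
#'   \code{path}.
#' @export
writePhantomSpec <- function(spec, path) {
  validObject(spec)
  yaml::write_yaml(list(
    image_side = spec@imageSide,
    n_frames = spec@nFrames,
    chamber_centers = lapply(seq_len(nrow(spec@chamberCenters)),
                             function(i) as.numeric(spec@chamberCenters[i, ])),
    chamber_base_radii = as.numeric(spec@chamberBaseRadii),
    pulsation_amplitude = spec@pulsationAmplitude,
    aorta_center = as.numeric(spec@aortaCenter),
    aorta_radius = spec@aortaRadius,
    noise_sigma = spec@noiseSigma,
    seed = spec@seed
  ), path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  y <- yaml::read_yaml(path)
  phantomSpec(
    imageSide = y$image_side, nFrames = y$n_frames,
    chamberCenters = do.call(rbind, y$chamber_centers),
    chamberBaseRadii = unlist(y$chamber_base_radii),
    pulsationAmplitude = y$pulsation_amplitude,
    aortaCenter = unlist(y$aorta_center), aortaRadius = y$aorta_radius,
    noiseSigma = y$noise_sigma, seed = y$seed)
}
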