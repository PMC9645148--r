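test_that("phantom generation is deterministic for a fixed seed", {
  a <- generatePhantom(smallPhantomSpec(seed = 7))
  b <- generatePhantom(smallPhantomSpec(seed = 7))
  expect_identical(frames(a), frames(b))
  expect_identical(masks(a), masks(b))
  d <- generatePhantom(smallPhantomSpec(seed = 8))
  expect_false(identical(frames(a), frames(d)))
})

test_that("a non-pulsating noiseless phantom is static", {
  cs <- generatePhantom(smallPhantomSpec(seed = 1, noiseSigma = 0,
                                         pulsationAmplitude = 0))
  fr <- frames(cs)
  for (t in 2:dim(fr)[3])
    expect_identical(fr[, , t], fr[, , 1])
  expect_true(all(temporalStdDev(cs) == 0))
})

test_that("pulsation creates temporal variance exactly on the swept annulus", {
  sp <- phantomSpec(imageSide = 96L, nFrames = 32L,
                    chamberCenters = rbind(right_atrium = c(55, 55),
                                           left_atrium = c(40, 22)),
                    chamberBaseRadii = c(12, 9), pulsationAmplitude = 0.2,
                    aortaCenter = c(20, 66), aortaRadius = 7,
                    noiseSigma = 0, seed = 3)
  cs <- generatePhantom(sp)
  sd_map <- temporalStdDev(cs)
  # the map maximum lies inside one of the chamber annuli
  peak <- which(sd_map == max(sd_map), arr.ind = TRUE)[1, ]
  ctr <- sp@chamberCenters
  rad <- sp@chamberBaseRadii
  amp <- sp@pulsationAmplitude
  inAnnulus <- vapply(1:2, function(k) {
    d <- sqrt(sum((peak - ctr[k, ])^2))
    d >= rad[k] * (1 - amp) - 1 && d <= rad[k] * (1 + amp) + 1
  }, logical(1))
  expect_true(any(inAnnulus))
  # strictly positive across every swept annulus pixel, zero far away
  rr <- matrix(seq_len(96), 96, 96)
  cc <- matrix(seq_len(96), 96, 96, byrow = TRUE)
  far <- rep(TRUE, 96 * 96)
  for (k in 1:2) {
    d <- sqrt((rr - ctr[k, 1])^2 + (cc - ctr[k, 2])^2)
    swept <- d >= rad[k] * (1 - amp) + 1 & d <= rad[k] * (1 + amp) - 1
    expect_true(all(sd_map[swept] > 0))
    far <- far & d > rad[k] * (1 + amp) + 2
  }
  d <- sqrt((rr - sp@aortaCenter[1])^2 + (cc - sp@aortaCenter[2])^2)
  far <- far & d > sp@aortaRadius + 2
  expect_true(all(sd_map[far] == 0))
})

test_that("mask pixels lie inside their structure's analytic circle", {
  sp <- smallPhantomSpec(seed = 5)
  cs <- generatePhantom(sp)
  radii <- phantomRadii(sp)
  centers <- rbind(sp@chamberCenters, aorta = sp@aortaCenter)
  labs <- cineClassLabels()
  rr <- matrix(seq_len(64), 64, 64)
  cc <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  for (t in c(1L, 3L, 8L)) {
    mk <- masks(cs)[, , t]
    for (k in 1:3) {
      d2 <- (rr - centers[k, 1])^2 + (cc - centers[k, 2])^2
      sel <- mk == unname(labs[rownames(centers)[k]])
      expect_true(all(d2[sel] <= radii[t, k]^2))
    }
  }
})

test_that("geometry overflow is reported with the offending structure", {
  expect_error(
    phantomSpec(imageSide = 64L, nFrames = 8L,
                chamberCenters = rbind(right_atrium = c(60, 32),
                                       left_atrium = c(20, 16)),
                chamberBaseRadii = c(8, 6), pulsationAmplitude = 0.2,
                aortaCenter = c(16, 48), aortaRadius = 5, seed = 1),
    "right_atrium")
})

test_that("sampled acquisition parameters honour the clinical ranges", {
  for (s in 1:8) {
    sp <- phantomSpec(seed = s)
    expect_gte(sp@nFrames, 28L); expect_lte(sp@nFrames, 40L)
    expect_gte(sp@imageSide, 235L); expect_lte(sp@imageSide, 263L)
  }
})

test_that("NIfTI round-trip preserves frames, masks and spacing", {
  cs <- generatePhantom(smallPhantomSpec(seed = 2))
  pre <- file.path(withr::local_tempdir(), "seq")
  writeCineNIfTI(cs, pre)
  back <- readCineNIfTI(pre)
  expect_equal(frames(back), frames(cs), tolerance = 1e-6)
  expect_identical(masks(back), masks(cs))
  expect_equal(pixelSpacing(back), pixelSpacing(cs))
})

test_that("malformed NIfTI input raises a format error", {
  pre <- file.path(withr::local_tempdir(), "bad")
  writeLines("not a nifti", paste0(pre, "_frames.nii.gz"))
  suppressWarnings(expect_error(readCineNIfTI(pre), "malformed"))
  expect_error(readCineNIfTI(file.path(tempdir(), "nonexistent")),
               "no cine frames")
})

test_that("masks with undeclared labels are rejected on construction", {
  fr <- array(0, c(4, 4, 2))
  mk <- array(0L, c(4, 4, 2))
  mk[1, 1, 1] <- 5L
  expect_error(CineSequence(fr, mk), "undeclared class labels")
})

test_that("PNG stack round-trip restores intensities and labels", {
  cs <- generatePhantom(smallPhantomSpec(seed = 4, nFrames = 3L))
  dir <- withr::local_tempdir()
  writeCinePNG(cs, dir)
  back <- readCinePNG(dir)
  expect_lt(max(abs(frames(back) - frames(cs))), 0.01)
  expect_identical(unname(masks(back)), unname(masks(cs)))
})

test_that("PhantomSpec YAML serialization round-trips", {
  sp <- smallPhantomSpec(seed = 11)
  path <- withr::local_tempfile(fileext = ".yaml")
  writePhantomSpec(sp, path)
  back <- readPhantomSpec(path)
  expect_equal(back@chamberCenters, unname(sp@chamberCenters),
               ignore_attr = TRUE)
  expect_equal(back@aortaCenter, sp@aortaCenter)
  expect_identical(back@seed, sp@seed)
  expect_identical(frames(generatePhantom(back)),
                   frames(generatePhantom(sp)))
})
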