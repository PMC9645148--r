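# A tiny in-memory dataset: 32x32 centre crops of small phantoms.
tinyTrainingData <- function(n = 8L, seed = 1L) {
  imgs <- list(); msks <- list()
  for (k in seq_len(n)) {
    cs <- generatePhantom(smallPhantomSpec(seed = seed * 50L + k))
    fr <- frames(cs)[17:48, 17:48, 1]
    imgs[[k]] <- (fr - mean(fr)) / sd(as.vector(fr))
    msks[[k]] <- masks(cs)[17:48, 17:48, 1]
  }
  list(images = imgs, masks = msks)
}

test_that("training reduces the loss on a small phantom set", {
  d <- tinyTrainingData()
  net <- esaUNet(inputSide = 32, baseChannels = 4, seed = 1)
  fit <- trainESAUNet(net, d$images, d$masks, epochs = 5, seed = 1)
  expect_identical(nrow(fit$log), 5L)
  expect_lt(fit$log$loss[5], fit$log$loss[1])
  expect_true(all(is.finite(fit$log$loss)))
})

test_that("a fixed seed reproduces the loss trajectory exactly", {
  d <- tinyTrainingData(n = 4)
  net <- esaUNet(inputSide = 32, baseChannels = 2, seed = 3)
  f1 <- trainESAUNet(net, d$images, d$masks, epochs = 2, seed = 11)
  f2 <- trainESAUNet(net, d$images, d$masks, epochs = 2, seed = 11)
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("degenerate training inputs abort with a diagnostic", {
  net <- esaUNet(inputSide = 32, baseChannels = 2, seed = 1)
  expect_error(trainESAUNet(net, list(), list()), "empty")
  d <- tinyTrainingData(n = 2)
  expect_error(trainESAUNet(net, d$images, d$masks[1]), "pair up")
})

test_that("validation Dice is logged and checkpoints are written", {
  d <- tinyTrainingData(n = 6)
  net <- esaUNet(inputSide = 32, baseChannels = 4, seed = 2)
  ck <- withr::local_tempfile(fileext = ".rds")
  fit <- trainESAUNet(net, d$images[1:4], d$masks[1:4],
                      valImages = d$images[5:6], valMasks = d$masks[5:6],
                      epochs = 3, seed = 2, checkpointPath = ck)
  expect_true(all(!is.na(fit$log$valDSC)))
  expect_true(file.exists(ck))
  best <- readRDS(ck)
  expect_s3_class(best, "ESAUNet")
})

test_that("foreground Dice scores perfect and disjoint masks correctly", {
  m <- matrix(sample(0:3, 64, TRUE), 8, 8)
  expect_equal(foregroundDice(m, m), 1)
  a <- matrix(0L, 8, 8); a[1:4, ] <- 1L
  b <- matrix(0L, 8, 8); b[5:8, ] <- 1L
  # class 1 disjoint (dice 0), classes 2 and 3 absent from both (dice 1)
  expect_equal(foregroundDice(a, b), 2 / 3)
})

test_that("augmentation preserves shapes and the label set", {
  cs <- generatePhantom(smallPhantomSpec(seed = 9))
  img <- frames(cs)[, , 1]; mk <- masks(cs)[, , 1]
  set.seed(1)
  au <- cardioseg:::.augmentSample(img, mk)
  expect_identical(dim(au$img), dim(img))
  expect_identical(dim(au$mask), dim(mk))
  expect_true(all(au$mask %in% 0:3))
})
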