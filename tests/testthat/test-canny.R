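test_that("temporal std-dev handles closed-form cases", {
  expect_true(all(temporalStdDev(array(3.7, c(4, 4, 6))) == 0))
  a <- array(rep(c(0, 1), each = 9), c(3, 3, 2))
  expect_true(all(abs(temporalStdDev(a) - 0.5) < 1e-12))
  expect_error(temporalStdDev(array(0, c(3, 3, 1))), "at least 2 frames")
})

test_that("gaussian smoothing preserves constants and normalizes mass", {
  img <- matrix(2.5, 16, 16)
  expect_equal(gaussianSmooth(img, 1.3), img)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- gaussianSmooth(imp, 2)
  expect_lt(abs(sum(sm) - 1), 1e-6)
  expect_true(all(sm >= 0))
  expect_error(gaussianSmooth(img, 0), "positive")
  expect_error(gaussianSmooth(img, -1), "positive")
})

test_that("wider smoothing flattens a step edge more", {
  step <- matrix(0, 20, 20); step[, 11:20] <- 1
  g1 <- max(sobelGradients(gaussianSmooth(step, 0.8))@magnitude)
  g2 <- max(sobelGradients(gaussianSmooth(step, 2.5))@magnitude)
  expect_lt(g2, g1)
})

test_that("the stored Sobel kernels are the canonical 3x3 pair", {
  k <- sobelKernels()
  expect_identical(k$Sx,
    matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE))
  expect_identical(k$Sy,
    matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE))
  expect_identical(k$Sx, t(k$Sy))
})

test_that("sobel gradients vanish on constants and hit 4 on a unit step", {
  g0 <- sobelGradients(matrix(1.4, 10, 10))
  expect_lt(max(g0@magnitude), 1e-12)
  # vertical step edge: left half 0, right half 1
  step <- matrix(0, 12, 12); step[, 7:12] <- 1
  g <- sobelGradients(step)
  # interior pixels of the two columns flanking the step see |gx| = 4
  expect_true(all(abs(abs(g@gx[3:10, 6:7]) - 4) < 1e-12))
  expect_true(all(abs(g@gy[3:10, 6:7]) < 1e-12))
  expect_true(all(abs(g@magnitude[3:10, 6:7] - 4) < 1e-12))
  expect_error(sobelGradients(matrix(0, 2, 5)), "at least 3 x 3")
})

test_that("gradient directions quantize to the eight compass angles", {
  set.seed(1)
  g <- sobelGradients(matrix(runif(400), 20, 20))
  expect_true(all(g@direction %in% seq(0, 315, by = 45)))
  gp <- sobelGradients(matrix(runif(400), 20, 20), direction = "printed")
  expect_true(all(gp@direction %in% seq(0, 315, by = 45)))
})

test_that("non-maximum suppression keeps thin ridges and drops shoulders", {
  # single-pixel-wide vertical ridge: already thin, survives unchanged
  m <- matrix(0, 9, 9); m[, 5] <- 3
  gf <- new("GradientField", gx = m, gy = m * 0, magnitude = m,
            direction = matrix(0, 9, 9))
  expect_identical(nonMaxSuppression(gf), m)
  # 3-pixel-wide ramp ridge with a unique maximal column
  m3 <- matrix(0, 9, 9); m3[, 4] <- 1; m3[, 5] <- 2; m3[, 6] <- 1
  gf3 <- new("GradientField", gx = m3, gy = m3 * 0, magnitude = m3,
             direction = matrix(0, 9, 9))
  out <- nonMaxSuppression(gf3)
  expect_true(all(out[, 5] == 2))
  expect_true(all(out[, c(4, 6)] == 0))
  # all-zero magnitude stays all-zero
  z <- matrix(0, 5, 5)
  gfz <- new("GradientField", gx = z, gy = z, magnitude = z,
             direction = z)
  expect_identical(nonMaxSuppression(gfz), z)
})

test_that("hysteresis applies the 2:1 default ratio and links weak chains", {
  nms <- matrix(0, 5, 5)
  em <- hysteresisThreshold(nms, t1 = 0.2)
  expect_equal(em@t2, 0.1)
  # isolated weak pixel with no strong neighbour is dropped
  nms[3, 3] <- 0.15
  em <- hysteresisThreshold(nms, 0.2)
  expect_false(any(edgeFinal(em)))
  # a weak chain touching one strong pixel is kept whole
  nms <- matrix(0, 5, 5)
  nms[2, 1] <- 0.5                      # strong
  nms[cbind(c(3, 4, 5), c(2, 3, 4))] <- 0.15  # weak diagonal chain
  nms[1, 5] <- 0.15                     # disconnected weak pixel
  em <- hysteresisThreshold(nms, 0.2)
  expect_identical(edgeFinal(em), hysteresisOracle(nms, 0.2, 0.1))
  expect_true(all(edgeFinal(em)[cbind(c(2, 3, 4, 5), c(1, 2, 3, 4))]))
  expect_false(edgeFinal(em)[1, 5])
  expect_error(hysteresisThreshold(nms, 0.1, 0.2), "t1 > t2")
})

test_that("hysteresis matches the flood-fill oracle on random fixtures", {
  for (s in 1:10) {
    set.seed(100 + s)
    nms <- matrix(rexp(32 * 32, rate = 8), 32, 32)
    nms[runif(32 * 32) < 0.6] <- 0
    t1 <- as.numeric(quantile(nms[nms > 0], 0.8))
    em <- hysteresisThreshold(nms, t1)
    expect_identical(edgeFinal(em), hysteresisOracle(nms, t1, t1 / 2))
    # strong/weak partition invariants
    expect_false(any(edgeStrong(em) & edgeWeak(em)))
    expect_true(all(edgeFinal(em)[edgeStrong(em)]))
  }
})

test_that("raising the upper threshold never adds edge pixels", {
  set.seed(42)
  img <- gaussianSmooth(matrix(runif(40 * 40), 40, 40), 1)
  nms <- nonMaxSuppression(sobelGradients(img))
  t1s <- as.numeric(quantile(nms[nms > 0], c(0.5, 0.7, 0.9)))
  prev <- NULL
  for (t1 in t1s) {
    fin <- edgeFinal(hysteresisThreshold(nms, t1))
    if (!is.null(prev)) expect_true(all(prev | !fin))  # fin subset of prev
    prev <- fin
  }
})
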