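test_that("zero pairwise weight reduces refinement to the argmax", {
  set.seed(1)
  probs <- array(runif(8 * 8 * 4), c(8, 8, 4))
  probs <- probs / array(rep(apply(probs, c(1, 2), sum), 4), dim(probs))
  img <- matrix(runif(64), 8, 8)
  cfg <- crfConfig(pairwiseWeight = 0)
  expect_identical(crfRefine(probs, img, cfg), probsToMask(probs))
})

test_that("a lone low-confidence outlier flips to the surrounding class", {
  probs <- array(0.05 / 3, c(8, 8, 4))
  probs[, , 1] <- 0.95                      # confident background
  probs[4, 4, ] <- c(0.45, 0.55, 0, 0)      # weak wrong vote for class 1
  img <- matrix(0.5, 8, 8)                  # uniform image
  out <- crfRefine(probs, img, crfConfig(pairwiseWeight = 2))
  expect_identical(out[4, 4], 0L)
  expect_true(all(out == 0L))
})

test_that("inference reaches a fixed point", {
  fx <- crfPhantomFixture(seed = 3)
  cfg10 <- crfConfig(pairwiseWeight = 2, nIterations = 10)
  cfg20 <- crfConfig(pairwiseWeight = 2, nIterations = 20)
  expect_identical(crfRefine(fx$probs, fx$img, cfg10),
                   crfRefine(fx$probs, fx$img, cfg20))
})

test_that("refinement is deterministic and shape-checked", {
  fx <- crfPhantomFixture(seed = 4)
  cfg <- crfConfig()
  expect_identical(crfRefine(fx$probs, fx$img, cfg),
                   crfRefine(fx$probs, fx$img, cfg))
  expect_error(crfRefine(fx$probs, fx$img[1:10, 1:10], cfg),
               "disagree in size")
})

test_that("energy is zero-pairwise for uniform labels and counts flips", {
  h <- 8; K <- 4
  probs <- array(1 / K, c(h, h, K))
  img <- matrix(0.5, h, h)
  labs <- matrix(1L, h, h)
  cfg <- crfConfig(pairwiseWeight = 2, neighborhood = 4L)
  eUniform <- crfEnergy(labs, probs, img, cfg)
  expect_equal(eUniform, -sum(log(rep(1 / K, h * h))))
  # flipping one interior pixel adds (neighbourhood size) * w * modulation
  labs2 <- labs; labs2[4, 4] <- 2L
  expect_equal(crfEnergy(labs2, probs, img, cfg) - eUniform,
               4 * 2 * exp(0))
  cfg8 <- crfConfig(pairwiseWeight = 2, neighborhood = 8L)
  expect_equal(crfEnergy(labs2, probs, img, cfg8) - eUniform,
               8 * 2 * exp(0))
})

test_that("refinement does not increase the CRF energy on phantoms", {
  cfg <- crfConfig(pairwiseWeight = 2)
  for (s in 1:8) {
    fx <- crfPhantomFixture(seed = s)
    argmax <- probsToMask(fx$probs)
    refined <- crfRefine(fx$probs, fx$img, cfg)
    expect_lte(crfEnergy(refined, fx$probs, fx$img, cfg),
               crfEnergy(argmax, fx$probs, fx$img, cfg))
  }
})

test_that("refinement repairs boundary noise (Dice direction)", {
  cfg <- crfConfig(pairwiseWeight = 2)
  gains <- vapply(1:8, function(s) {
    fx <- crfPhantomFixture(seed = s)
    refined <- crfRefine(fx$probs, fx$img, cfg)
    foregroundDice(refined, fx$mask) -
      foregroundDice(probsToMask(fx$probs), fx$mask)
  }, numeric(1))
  expect_gt(mean(gains), 0)
})

test_that("refinement introduces no class outside the top-2 support", {
  for (s in 1:5) {
    fx <- crfPhantomFixture(seed = s)
    refined <- crfRefine(fx$probs, fx$img, crfConfig(pairwiseWeight = 2))
    d <- dim(fx$probs)
    pm <- matrix(fx$probs, d[1] * d[2], d[3])
    top2 <- unique(as.vector(apply(pm, 1, function(r)
      order(r, decreasing = TRUE)[1:2]))) - 1L
    expect_true(all(unique(as.vector(refined)) %in%
                      union(unique(as.vector(probsToMask(fx$probs))), top2)))
  }
})

test_that("crf configuration rejects invalid settings", {
  expect_error(crfConfig(pairwiseWeight = -1), "pairwiseWeight")
  expect_error(crfConfig(intensityScale = 0), "intensityScale")
  expect_error(crfConfig(nIterations = 0), "nIterations")
  expect_error(crfConfig(neighborhood = 6), "neighborhood")
})
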