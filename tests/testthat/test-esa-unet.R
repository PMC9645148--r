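test_that("encoder level shapes halve spatially and double in channels", {
  net <- esaUNet(inputSide = 64, baseChannels = 4, seed = 1)
  set.seed(2)
  feats <- encoderForward(net, matrix(rnorm(64 * 64), 64, 64))
  expect_length(feats, 5)
  for (l in 1:5)
    expect_identical(dim(feats[[l]]),
                     as.integer(c(64 / 2^(l - 1), 64 / 2^(l - 1),
                                  4 * 2^(l - 1))))
  # the classic configuration: 128 px input, base 64 -> 8x8x1024 bottleneck
  big <- esaUNet(inputSide = 128, baseChannels = 64, seed = 1)
  expect_identical(unname(big$config$bottleneck), c(8L, 8L, 1024L))
  expect_identical(big$config$widths, as.integer(64 * 2^(0:4)))
})

test_that("indivisible input sizes are rejected by name", {
  expect_error(esaUNet(inputSide = 100), "divisible by 16")
  net <- esaUNet(inputSide = 32, baseChannels = 4)
  expect_error(encoderForward(net, matrix(0, 40, 40)), "divisible by 16")
  expect_error(encoderForward(net, matrix(0, 48, 48)), "built for")
})

test_that("zero input with zero-initialized convolutions gives zero features", {
  net <- esaUNet(inputSide = 32, baseChannels = 4, seed = 1)
  net$params <- lapply(net$params, function(p) p * 0)
  feats <- encoderForward(net, matrix(0, 32, 32))
  for (f in feats) expect_true(all(f == 0))
})

test_that("low-rank factors are sigmoid-bounded with GAP means", {
  net <- esaUNet(inputSide = 32, baseChannels = 4, seed = 3)
  set.seed(4)
  x <- array(rnorm(2 * 2 * 64), c(2, 2, 64))
  for (i in 1:4) {
    f <- lowRankGenerate(net, x, i)
    expect_length(f$Q, 2); expect_length(f$K, 2); expect_length(f$V, 64)
    expect_true(all(f$Q > 0 & f$Q < 1))
    expect_true(all(f$K > 0 & f$K < 1))
    expect_true(all(f$V > 0 & f$V < 1))
  }
  # GAP slices: element m of the height profile is mean(x[m, , ])
  cache <- cardioseg:::.lrFactorsFwd(net$params, x, 1)$cache
  expect_equal(cache$gq, c(mean(x[1, , ]), mean(x[2, , ])))
  expect_equal(cache$gk, c(mean(x[, 1, ]), mean(x[, 2, ])))
  expect_equal(cache$gv, colMeans(matrix(x, 4, 64)))
  # a constant input pools to a constant profile
  cc <- cardioseg:::.lrFactorsFwd(net$params, array(1.5, c(2, 2, 64)),
                                  1)$cache
  expect_true(all(cc$gq == 1.5) && all(cc$gv == 1.5))
})

test_that("rank-one attention maps match the dense outer-product oracle", {
  set.seed(9)
  for (rep in 1:5) {
    Q <- runif(8); K <- runif(8)
    A <- attentionMap(list(Q = Q, K = K, V = runif(4)))
    expect_lt(max(abs(A - denseAttentionOracle(Q, K))), 1e-6)
    expect_lt(abs(sum(A) - 1), 1e-12)
    expect_true(all(A >= 0))
  }
  # row-wise variant normalizes every row instead
  Ar <- attentionMap(list(Q = runif(8), K = runif(8)), softmaxAxis = "row")
  expect_equal(rowSums(Ar), rep(1, 8))
})

test_that("attention with zeroed projection is the identity", {
  net <- esaUNet(inputSide = 32, baseChannels = 4, seed = 5)
  set.seed(6)
  x <- array(rnorm(2 * 2 * 64), c(2, 2, 64))
  f <- lowRankGenerate(net, x, 1)
  net$params[["lrsar1.out.W"]] <- net$params[["lrsar1.out.W"]] * 0
  net$params[["lrsar1.out.b"]] <- net$params[["lrsar1.out.b"]] * 0
  expect_identical(lowRankAttention(net, x, f, 1), x)
})

test_that("lrsar limits: zero lambdas give identity, s = 1 reduces", {
  net <- esaUNet(inputSide = 32, baseChannels = 4, seed = 7)
  set.seed(8)
  x <- array(rnorm(2 * 2 * 64), c(2, 2, 64))
  net0 <- net
  net0$params[["lrsar.lambda"]] <- rep(0, 4)
  expect_equal(lrsarForward(net0, x), x)
  net1 <- esaUNet(inputSide = 32, baseChannels = 4,
                  lrsar = lrsarConfig(s = 1), seed = 7)
  net1$params[["lrsar.lambda"]] <- 1
  f <- lowRankGenerate(net1, x, 1)
  expect_equal(lrsarForward(net1, x), lowRankAttention(net1, x, f, 1))
})

test_that("literal recombination scales the input by the lambda sum", {
  net <- esaUNet(inputSide = 32, baseChannels = 4,
                 lrsar = lrsarConfig(mode = "literal"), seed = 7)
  set.seed(8)
  x <- array(rnorm(2 * 2 * 64), c(2, 2, 64))
  net$params[["lrsar.lambda"]] <- rep(0, 4)
  expect_equal(lrsarForward(net, x), x * 0)
})

test_that("decoder restores resolution with per-pixel probabilities", {
  net <- esaUNet(inputSide = 64, baseChannels = 4, seed = 1)
  set.seed(2)
  x <- matrix(rnorm(64 * 64), 64, 64)
  probs <- predictProbs(net, x)
  expect_identical(dim(probs), c(64L, 64L, 4L))
  sums <- apply(probs, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(probs >= 0 & probs <= 1))
  # 128 in -> 128 out
  net128 <- esaUNet(inputSide = 128, baseChannels = 2, seed = 1)
  p128 <- predictProbs(net128, matrix(rnorm(128 * 128), 128, 128))
  expect_identical(dim(p128), c(128L, 128L, 4L))
})

test_that("gradients reach every parameter of the network", {
  net <- esaUNet(inputSide = 32, baseChannels = 4, seed = 2)
  set.seed(3)
  x <- matrix(rnorm(32 * 32), 32, 32)
  mk <- matrix(sample(0:3, 32 * 32, TRUE), 32, 32)
  fwd <- cardioseg:::.netFwd(net, x)
  ls <- cardioseg:::.segLoss(fwd$probs, fwd$logits, mk)
  g <- cardioseg:::.netBwd(net, fwd, ls$dlogits)
  expect_setequal(names(g), names(net$params))
  for (nm in names(g))
    expect_gt(max(abs(g[[nm]])), 0)
})

test_that("analytic and numeric gradients agree on a tiny net", {
  net <- esaUNet(inputSide = 32, baseChannels = 2, seed = 4)
  set.seed(5)
  x <- matrix(rnorm(32 * 32), 32, 32)
  mk <- matrix(sample(0:3, 32 * 32, TRUE), 32, 32)
  fwd <- cardioseg:::.netFwd(net, x)
  ls <- cardioseg:::.segLoss(fwd$probs, fwd$logits, mk)
  g <- cardioseg:::.netBwd(net, fwd, ls$dlogits)
  lossAt <- function(p) {
    n2 <- net; n2$params <- p
    f <- cardioseg:::.netFwd(n2, x)
    cardioseg:::.segLoss(f$probs, f$logits, mk)$loss
  }
  eps <- 1e-6
  for (nm in c("enc1.conv1.W", "enc3.proj.W", "lrsar.lambda",
               "lrsar2.fck.W", "dec2.conv.W", "final.W")) {
    p <- net$params
    p[[nm]][3] <- p[[nm]][3] + eps; up <- lossAt(p)
    p[[nm]][3] <- p[[nm]][3] - 2 * eps; dn <- lossAt(p)
    num <- (up - dn) / (2 * eps)
    expect_lt(abs(num - g[[nm]][3]) / max(abs(num), 1e-8), 1e-3)
  }
})

test_that("attention cost is linear while dense attention is quadratic", {
  # Theta(s*H*W*C): doubling C doubles the count, doubling H*W doubles it
  expect_equal(lrsarMacs(8, 8, 128, 4) / lrsarMacs(8, 8, 64, 4), 2,
               tolerance = 0.03)
  expect_equal(lrsarMacs(16, 16, 64, 4) / lrsarMacs(8, 16, 64, 4), 2,
               tolerance = 0.01)
  expect_equal(lrsarMacs(8, 8, 64, 8) / lrsarMacs(8, 8, 64, 4), 2)
  # dense/LRSAR advantage grows linearly with H*W
  ratio <- function(side) denseAttentionMacs(side, side, 64) /
    lrsarMacs(side, side, 64, 4)
  expect_equal(ratio(16) / ratio(8), 4, tolerance = 0.01)
  expect_equal(ratio(32) / ratio(8), 16, tolerance = 0.01)
})
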