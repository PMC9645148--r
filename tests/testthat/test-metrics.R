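test_that("the closed-form confusion fixture yields the textbook values", {
  cm <- matrix(c(8L, 2L, 88L, 2L), 1,
               dimnames = list("class1", c("tp", "fp", "tn", "fn")))
  m <- computeMetrics(cm, macro = "all")[1, ]
  expect_equal(m$pre, 0.8)
  expect_equal(m$re, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$acc, 0.96)
  expect_equal(m$iou, 8 / 12, tolerance = 1e-12)
  expect_equal(m$dsc, 16 / 20)
})

test_that("perfect prediction scores 1 on all six metrics", {
  set.seed(2)
  mk <- matrix(sample(0:3, 256, TRUE), 16, 16)
  m <- computeMetrics(confusionCounts(mk, mk))
  expect_true(all(abs(as.matrix(m[, -1]) - 1) < 1e-12))
})

test_that("total disagreement on a binary mask zeroes tp and tn", {
  ref <- matrix(rep(c(0L, 1L), 50), 10, 10)
  pred <- 1L - ref
  cm <- confusionCounts(pred, ref, numClasses = 2L)
  expect_identical(unname(cm[, "tp"]), c(0L, 0L))
  expect_identical(unname(cm[, "tn"]), c(0L, 0L))
  expect_equal(unname(rowSums(cm)), c(100, 100))
})

test_that("confusion counts match the per-pixel loop oracle", {
  set.seed(7)
  for (rep in 1:3) {
    pred <- matrix(sample(0:3, 256, TRUE), 16, 16)
    ref <- matrix(sample(0:3, 256, TRUE), 16, 16)
    expect_identical(confusionCounts(pred, ref), confusionOracle(pred, ref))
  }
  expect_error(confusionCounts(matrix(0L, 3, 3), matrix(0L, 4, 4)),
               "differ in shape")
})

test_that("row sums equal the pixel count for every class", {
  set.seed(8)
  pred <- matrix(sample(0:3, 400, TRUE), 20, 20)
  ref <- matrix(sample(0:3, 400, TRUE), 20, 20)
  expect_true(all(rowSums(confusionCounts(pred, ref)) == 400L))
})

test_that("dice and IoU obey their monotone link and symmetry", {
  set.seed(3)
  for (rep in 1:10) {
    pred <- matrix(sample(0:3, 144, TRUE, prob = c(5, 1, 1, 1)), 12, 12)
    ref <- matrix(sample(0:3, 144, TRUE, prob = c(5, 1, 1, 1)), 12, 12)
    m <- computeMetrics(confusionCounts(pred, ref), macro = "all")
    m <- m[m$class != "macro", ]   # the link is per class, not for means
    expect_equal(m$dsc, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
    # IoU and DSC are symmetric in (pred, ref)
    ms <- computeMetrics(confusionCounts(ref, pred), macro = "all")
    ms <- ms[ms$class != "macro", ]
    expect_equal(m$iou, ms$iou)
    expect_equal(m$dsc, ms$dsc)
  }
})

test_that("classes absent from both maps follow the empty-set convention", {
  pred <- matrix(0L, 5, 5)
  ref <- matrix(0L, 5, 5)
  m <- computeMetrics(confusionCounts(pred, ref))
  expect_true(all(as.matrix(m[m$class != "macro", -1]) == 1))
})

test_that("dataset evaluation averages per-case reports and exports CSV", {
  set.seed(5)
  refs <- lapply(1:4, function(i) matrix(sample(0:3, 64, TRUE), 8, 8))
  preds <- lapply(refs, function(r) {
    p <- r
    p[1, ] <- (p[1, ] + 1L) %% 4L
    p
  })
  csv <- withr::local_tempfile(fileext = ".csv")
  ev <- evaluateDataset(preds, refs, csvPath = csv)
  perCaseDsc <- ev$perCase$dsc[ev$perCase$class == "macro"]
  expect_equal(mean(perCaseDsc), unname(ev$macro["dsc"]), tolerance = 1e-12)
  back <- read.csv(csv)
  expect_equal(back$dsc, ev$perCase$dsc, tolerance = 1e-12)
  expect_error(evaluateDataset(preds[1:2], refs), "differ in length")
  # a single perfect case scores a perfect macro
  one <- evaluateDataset(refs[1], refs[1])
  expect_true(all(abs(one$macro - 1) < 1e-12))
})
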