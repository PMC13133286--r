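test_that("the scale factor is the RMS of the box dimensions", {
  expect_equal(scaleFactor(100, 100), 100)
  expect_equal(scaleFactor(300, 40), sqrt(45800))
  expect_equal(scaleFactor(BoundingBox(5, 5, 300, 40)), sqrt(45800))
  expect_error(scaleFactor(0, 0), class = "tpk_schema_error")
  set.seed(3)
  w <- runif(200, 0, 1000); h <- runif(200, 0, 1000)
  for (i in seq_along(w)) {
    expect_identical(scaleFactor(w[i], h[i]), scaleFactor(h[i], w[i]))
    expect_gte(scaleFactor(w[i], h[i])^2, w[i] * h[i] - 1e-9)
  }
})

test_that("the keypoint similarity matches its closed forms", {
  params <- OksParams()
  s <- 150
  gt <- tripletVec(100, 100, 2, 200, 150, 2, 260, 180, 1, 255, 120, 2)
  expect_equal(oks(gt, gt, s, params), 1)

  # one labelled keypoint displaced so d^2 = 2 s^2 kappa^2 -> exp(-1)
  kap <- params@kappa[1]
  d <- sqrt(2) * s * kap
  gt1 <- tripletVec(100, 100, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  pd1 <- tripletVec(100 + d, 100, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(oks(pd1, gt1, s, params), exp(-1), tolerance = 1e-12)

  # two labelled keypoints, one exact, one at d^2 = 2 s^2 kappa^2
  gt2 <- tripletVec(100, 100, 2, 300, 300, 2, 0, 0, 0, 0, 0, 0)
  pd2 <- tripletVec(100, 100, 2, 300 + d, 300, 2, 0, 0, 0, 0, 0, 0)
  expect_equal(oks(pd2, gt2, s, params), (1 + exp(-1)) / 2,
               tolerance = 1e-12)

  # unlabelled ground-truth keypoints contribute nothing
  pd3 <- tripletVec(100, 100, 2, 300 + d, 300, 2, 1e6, 1e6, 2, 0, 0, 0)
  expect_equal(oks(pd3, gt2, s, params), (1 + exp(-1)) / 2,
               tolerance = 1e-12)

  # predicted visibility codes are ignored
  pd4 <- pd2; pd4[seq(3, 12, 3)] <- 0
  expect_equal(oks(pd4, gt2, s, params), oks(pd2, gt2, s, params))

  # ground truth without labelled keypoints is an ignore signal
  expect_true(is.na(oks(pd2, rep(0, 12), s, params)))
})

test_that("similarity strictly decreases as one displacement grows", {
  params <- OksParams(); s <- 120
  gt <- tripletVec(100, 100, 2, 200, 150, 2, 260, 180, 2, 255, 120, 2)
  prev <- Inf
  for (d in c(0, 1, 5, 20, 80, 300)) {
    pd <- gt; pd[4] <- gt[4] + d
    val <- oks(pd, gt, s, params)
    expect_true(val < prev || d == 0)
    expect_gte(val, 0); expect_lte(val, 1)
    prev <- val
  }
})

test_that("tip-swap similarity is permutation-invariant and dominates", {
  params <- OksParams(); s <- 150
  # swapped tips with exact entry/hinge: perfect under tip-swap only
  gt <- tripletVec(100, 100, 2, 200, 150, 2, 260, 180, 2, 255, 120, 2)
  pd <- tripletVec(100, 100, 2, 200, 150, 2, 255, 120, 2, 260, 180, 2)
  expect_lt(oks(pd, gt, s, params), 1)
  expect_equal(oksTipSwap(pd, gt, s, params), 1)

  # rigid ground truth: the swap moves the labelled tip to the other slot
  gtr <- tripletVec(100, 100, 2, 200, 150, 2, 260, 180, 2, 0, 0, 0)
  pdr <- tripletVec(100, 100, 2, 200, 150, 2, 999, 999, 2, 260, 180, 2)
  brute <- max(oks(pdr, gtr, s, params),
               oks(pdr, tripletVec(100, 100, 2, 200, 150, 2,
                                   0, 0, 0, 260, 180, 2), s, params))
  expect_equal(oksTipSwap(pdr, gtr, s, params), brute)

  # dominance and argument-order symmetry of the max over random pairs
  set.seed(5)
  for (i in 1:200) {
    g <- tripletVec(runif(1, 0, 960), runif(1, 0, 540), sample(0:2, 1),
                    runif(1, 0, 960), runif(1, 0, 540), sample(0:2, 1),
                    runif(1, 0, 960), runif(1, 0, 540), sample(0:2, 1),
                    runif(1, 0, 960), runif(1, 0, 540), sample(1:2, 1))
    p <- g + rnorm(12, 0, 30)
    a <- oks(p, g, s, params)
    b <- oksTipSwap(p, g, s, params)
    expect_gte(b, a)
    # swapping the prediction's tips cannot change the best-of-two value
    ps <- as.numeric(t(matrix(p, 4, 3, byrow = TRUE)[c(1, 2, 4, 3), ]))
    expect_equal(oksTipSwap(ps, g, s, params), b)
  }
})

test_that("box IoU matches hand arithmetic", {
  expect_equal(iouBox(BoundingBox(0, 0, 2, 2), BoundingBox(0, 0, 2, 2)), 1)
  expect_equal(iouBox(BoundingBox(0, 0, 2, 2), BoundingBox(10, 10, 2, 2)), 0)
  expect_equal(iouBox(BoundingBox(0, 0, 2, 2), BoundingBox(1, 0, 2, 2)),
               2 / 6)
  expect_equal(iouBox(BoundingBox(0, 0, 0, 0), BoundingBox(0, 0, 0, 0)), 0)
})

test_that("greedy matching follows the reference protocol", {
  gt1 <- CocoAnnotation(1L, 1L,
                        tripletVec(100, 100, 2, 200, 150, 2, 260, 180, 2,
                                   255, 120, 2),
                        BoundingBox(80, 80, 200, 120))
  d1 <- ScoredDetection(1L, gt1@keypoints, 0.9)
  m <- greedyMatch(list(d1), list(gt1),
                   similarity = matrix(0.9, 1, 1), threshold = 0.5)
  expect_identical(m$detMatch, 1L)
  expect_identical(m$gtMatch, 1L)
  expect_false(m$detIgnore)

  # two detections competing for one gt: higher score wins
  d2 <- ScoredDetection(1L, gt1@keypoints, 0.8)
  m2 <- greedyMatch(list(d2, d1), list(gt1),
                    similarity = matrix(c(0.7, 0.9), 2, 1), threshold = 0.5)
  expect_identical(m2$detMatch, c(0L, 1L))
  expect_identical(m2$gtMatch, 2L)

  # detection matching only an ignore instance is excluded, not penalised
  gtIgn <- CocoAnnotation(1L, 2L, rep(0, 12), BoundingBox(0, 0, 100, 100))
  expect_identical(gtIgn@numKeypoints, 0L)
  m3 <- greedyMatch(list(d1), list(gtIgn),
                    similarity = matrix(0.8, 1, 1), threshold = 0.5)
  expect_true(m3$detIgnore)
})

test_that("perfect and absent detections give the extreme summaries", {
  batch <- simulateBatch(5, baseSeed = 40L, noiseSd = 0)
  ev <- evaluatePose(batch$gt, batch$dets)
  expect_equal(ev@apMean, 1); expect_equal(ev@arMean, 1)
  expect_equal(ev@ap050, 1); expect_equal(ev@ap075, 1)
  evb <- evaluateBbox(batch$gt, batch$dets)
  expect_equal(evb@apMean, 1); expect_equal(evb@arMean, 1)

  ev0 <- evaluatePose(batch$gt, list())
  expect_equal(ev0@apMean, 0); expect_equal(ev0@arMean, 0)

  # no evaluable ground truth: the -1 sentinel
  ds <- framesToCocoDataset(list(FrameAnnotation(poses = list(),
                                                 frameId = "empty")))
  evE <- evaluatePose(ds, list())
  expect_equal(evE@apMean, -1); expect_equal(evE@arMean, -1)
})

test_that("boxes at IoU 0.6 pass the 0.5 threshold and fail 0.75", {
  # gt box (0,0,100,100), det box (25,0,100,100): IoU = 7500/12500 = 0.6
  kp <- tripletVec(40, 40, 2, 50, 50, 2, 60, 60, 2, 70, 70, 2)
  gt <- new("CocoDataset",
            images = data.frame(id = 1L, file_name = "f", width = 960,
                                height = 540),
            annotations = list(CocoAnnotation(1L, 1L, kp,
                                              BoundingBox(0, 0, 100, 100))),
            categories = list(list(id = 1L, name = "surgical_instrument")))
  d <- ScoredDetection(1L, kp, 0.9, bbox = BoundingBox(25, 0, 100, 100))
  expect_equal(iouBox(d@bbox, BoundingBox(0, 0, 100, 100)), 0.6)
  ev <- evaluateBbox(gt, list(d))
  i50 <- which(abs(ev@thresholds - 0.5) < 1e-9)
  i75 <- which(abs(ev@thresholds - 0.75) < 1e-9)
  expect_equal(mean(ev@precision[i50, ]), 1)
  expect_equal(mean(ev@precision[i75, ]), 0)
})

test_that("AP and AR are non-increasing in the threshold", {
  batch <- simulateBatch(10, baseSeed = 70L, noiseSd = 8, dropProb = 0.1)
  for (ev in list(evaluatePose(batch$gt, batch$dets),
                  evaluateBbox(batch$gt, batch$dets))) {
    apPerThr <- rowMeans(ev@precision)
    expect_true(all(diff(apPerThr) <= 1e-12))
    expect_true(all(diff(ev@recall) <= 1e-12))
    expect_gte(ev@ap050, ev@ap075)
    expect_gte(ev@ar050, ev@ar075)
  }
})

test_that("the summary table mirrors the benchmark column layout", {
  batch <- simulateBatch(3, baseSeed = 90L, noiseSd = 4)
  tab <- summaryTable(evaluatePose(batch$gt, batch$dets))
  expect_identical(names(tab),
                   c("protocol", "AP", "AP50", "AP75", "AR", "AR50", "AR75"))
  expect_identical(tab$protocol, "OKS")
  tf <- tempfile(fileext = ".json")
  writeEvalSummary(evaluatePose(batch$gt, batch$dets), tf)
  doc <- jsonlite::fromJSON(tf)
  expect_equal(doc$summary$ap, tab$AP)
  expect_equal(doc$schema_version, 1L)
})

test_that("detections with unresolvable image ids are rejected", {
  batch <- simulateBatch(2, baseSeed = 95L)
  bad <- ScoredDetection(99L, rep(0, 12), 0.5)
  expect_error(evaluatePose(batch$gt, c(batch$dets, bad)),
               class = "tpk_schema_error")
})
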