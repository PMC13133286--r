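test_that("visibility codes follow the three-state taxonomy", {
  expect_equal(visibilityCode(Keypoint(480, 270, "hinge", "visible")), 2)
  expect_equal(visibilityCode(Keypoint(-30, 100, "entry", "occluded")), 0)
  # occluded but inside the rectangular frame (e.g. under the circular
  # vignette) keeps its positive coordinates and gets v = 1
  expect_equal(visibilityCode(Keypoint(20, 20, "hinge", "occluded")), 1)
  expect_equal(visibilityCode(missingKeypoint("tip2")), 0)
  # half-open bound: x = width is outside
  expect_equal(visibilityCode(Keypoint(960, 100, "tip1", "occluded"),
                              960, 540), 0)
})

test_that("keypoint boxes apply extent, margin and clipping", {
  p <- ToolPose(entry = Keypoint(100, 200, "entry"),
                hinge = Keypoint(400, 250, "hinge"),
                tip1 = Keypoint(380, 300, "tip1"),
                instanceId = 1L)
  expect_equal(unname(bboxVector(keypointBbox(p, 960, 540, 20))),
               c(80, 180, 340, 140))
  # clipping at the frame origin
  p2 <- ToolPose(entry = Keypoint(5, 5, "entry"),
                 hinge = Keypoint(400, 250, "hinge"),
                 instanceId = 1L)
  bb <- bboxVector(keypointBbox(p2, 960, 540, 20))
  expect_equal(unname(bb[c("xmin", "ymin")]), c(0, 0))
  # degenerate single-point extent at margin 0
  p3 <- ToolPose(tip1 = Keypoint(10, 10, "tip1"), instanceId = 1L)
  expect_equal(unname(bboxVector(keypointBbox(p3, 960, 540, 0))),
               c(10, 10, 0, 0))
  # occluded-outside-frame keypoints (v = 0) never contribute
  p4 <- ToolPose(entry = Keypoint(-300, -300, "entry", "occluded"),
                 hinge = Keypoint(400, 250, "hinge"),
                 instanceId = 1L)
  expect_equal(unname(bboxVector(keypointBbox(p4, 960, 540, 20))),
               c(380, 230, 40, 40))
  # no labelled keypoint at all is an error
  expect_error(keypointBbox(ToolPose(instanceId = 1L), 960, 540),
               class = "tpk_schema_error")
})

test_that("adding a keypoint never shrinks the box", {
  set.seed(7)
  for (i in 1:50) {
    xs <- runif(3, 0, 960); ys <- runif(3, 0, 540)
    p3 <- ToolPose(entry = Keypoint(xs[1], ys[1], "entry"),
                   hinge = Keypoint(xs[2], ys[2], "hinge"),
                   tip1 = Keypoint(xs[3], ys[3], "tip1"),
                   instanceId = 1L)
    p4 <- ToolPose(entry = Keypoint(xs[1], ys[1], "entry"),
                   hinge = Keypoint(xs[2], ys[2], "hinge"),
                   tip1 = Keypoint(xs[3], ys[3], "tip1"),
                   tip2 = Keypoint(runif(1, 0, 960), runif(1, 0, 540), "tip2"),
                   instanceId = 1L)
    a <- bboxVector(keypointBbox(p3)); b <- bboxVector(keypointBbox(p4))
    expect_lte(b[["xmin"]], a[["xmin"]])
    expect_lte(b[["ymin"]], a[["ymin"]])
    expect_gte(b[["xmin"]] + b[["w"]], a[["xmin"]] + a[["w"]])
    expect_gte(b[["ymin"]] + b[["h"]], a[["ymin"]] + a[["h"]])
    # clipped box lies within the frame
    expect_gte(b[["xmin"]], 0); expect_gte(b[["ymin"]], 0)
    expect_lte(b[["xmin"]] + b[["w"]], 960)
    expect_lte(b[["ymin"]] + b[["h"]], 540)
  }
})

test_that("pose-to-COCO conversion fills counts, box and diagonal area", {
  rigid <- ToolPose(entry = Keypoint(700, 20, "entry"),
                    hinge = Keypoint(500, 250, "hinge"),
                    tip1 = Keypoint(460, 330, "tip1"),
                    instanceId = 1L)
  a <- poseToCoco(rigid, imageId = 1L, annId = 1L)
  expect_identical(a@numKeypoints, 3L)
  expect_equal(keypointTriplets(a)["tip2", ], c(x = 0, y = 0, v = 0))

  full <- poseToCoco(visiblePose(), 1L, 2L)
  expect_identical(full@numKeypoints, 4L)

  # area is the squared diagonal, not w * h
  ann <- CocoAnnotation(1L, 3L, keypoints = full@keypoints,
                        bbox = BoundingBox(0, 0, 300, 400))
  expect_equal(ann@area, 250000)
  expect_error(poseToCoco(ToolPose(instanceId = 1L)),
               class = "tpk_schema_error")
})

test_that("metric scale squared is half the stored diagonal area", {
  set.seed(11)
  for (i in 1:50) {
    scn <- genScene(SceneConfig(seed = 600L + i))
    ds <- framesToCocoDataset(list(scn$annotation))
    for (a in annotations(ds)) {
      expect_equal(scaleFactor(a@bbox)^2, a@area / 2, tolerance = 1e-12)
    }
  }
})

test_that("COCO half round trip is exact on random synthetic annotations", {
  n <- 0L
  for (s in 1:60) {
    scn <- genScene(SceneConfig(seed = 700L + s))
    fr <- scn$annotation
    for (pose in poses(fr)) {
      a <- poseToCoco(pose, 1L, 1L, fr@width, fr@height)
      b <- poseToCoco(cocoToPose(a), 1L, 1L, fr@width, fr@height)
      expect_identical(b@keypoints, a@keypoints)
      expect_identical(b@numKeypoints, a@numKeypoints)
      n <- n + 1L
    }
  }
  expect_gte(n, 100L)
})

test_that("visibility codes outside {0,1,2} are rejected", {
  kp <- tripletVec(1, 2, 2, 3, 4, 3, 0, 0, 0, 0, 0, 0)
  expect_error(CocoAnnotation(1L, 1L, kp, BoundingBox(0, 0, 10, 10)),
               class = "tpk_schema_error")
})

test_that("COCO dataset JSON survives a write/read cycle", {
  frames <- lapply(1:3, function(s) genScene(SceneConfig(seed = 800L + s),
                                             frameId = paste0("f", s))$annotation)
  ds <- framesToCocoDataset(frames)
  tf <- tempfile(fileext = ".json")
  writeCocoDataset(ds, tf)
  ds2 <- readCocoDataset(tf)
  expect_equal(images(ds2), images(ds))
  expect_length(annotations(ds2), length(annotations(ds)))
  for (k in seq_along(annotations(ds))) {
    a <- annotations(ds)[[k]]; b <- annotations(ds2)[[k]]
    expect_equal(b@keypoints, a@keypoints)
    expect_identical(b@numKeypoints, a@numKeypoints)
    expect_equal(bboxVector(b@bbox), bboxVector(a@bbox))
    expect_equal(b@area, a@area)
  }
  # num_keypoints invariant holds for everything read back
  for (b in annotations(ds2))
    expect_identical(b@numKeypoints,
                     as.integer(sum(b@keypoints[seq(3, 12, 3)] > 0)))
})

test_that("detection files survive a write/read cycle", {
  scn <- genScene(SceneConfig(seed = 900L))
  dets <- perturbPredictions(scn$annotation, noiseSd = 3, seed = 1L)
  tf <- tempfile(fileext = ".json")
  writeDetections(dets, tf)
  dets2 <- readDetections(tf)
  expect_length(dets2, length(dets))
  for (k in seq_along(dets)) {
    expect_equal(dets2[[k]]@keypoints, dets[[k]]@keypoints)
    expect_equal(dets2[[k]]@score, dets[[k]]@score)
    expect_equal(bboxVector(dets2[[k]]@bbox), bboxVector(dets[[k]]@bbox))
  }
})
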