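test_that("a four-node fully visible document parses to one pose", {
  doc <- jsonlite::toJSON(list(
    nodes = list(c(700, 20), c(500, 250), c(460, 330), c(545, 335)),
    tags = list("E:visible", "H:visible", "T1:visible", "T2:visible"),
    edges = list(c(0, 1), c(1, 2), c(1, 3)),
    transitions = list()
  ), auto_unbox = TRUE)
  fr <- parseRawJson(as.character(doc))
  expect_length(poses(fr), 1)
  p <- poses(fr)[[1]]
  expect_equal(kpX(entryPoint(p)), 700)
  expect_equal(kpTag(hingePoint(p)), "visible")
  expect_length(transitions(p), 0)
  expect_equal(validatePose(p, 960, 540), character(0))
})

test_that("illegal skeleton edges are rejected, legal ones accepted", {
  mkDoc <- function(edges) as.character(jsonlite::toJSON(list(
    nodes = list(c(700, 20), c(500, 250), c(460, 330), c(545, 335)),
    tags = list("E:visible", "H:visible", "T1:visible", "T2:visible"),
    edges = edges, transitions = list()
  ), auto_unbox = TRUE))
  # enumerate all node pairs; only E-H, H-T1, H-T2 (indices 0-1, 1-2, 1-3)
  legal <- list(c(0, 1), c(1, 2), c(1, 3))
  for (i in 0:2) for (j in (i + 1):3) {
    pair <- c(i, j)
    isLegal <- any(vapply(legal, function(l) all(l == pair), logical(1)))
    if (isLegal)
      expect_silent(parseRawJson(mkDoc(list(pair))))
    else
      expect_error(parseRawJson(mkDoc(list(pair))),
                   class = "tpk_schema_error")
  }
})

test_that("malformed documents raise classed errors", {
  expect_error(parseRawJson("{nope"), class = "tpk_parse_error")
  expect_error(parseRawJson('{"nodes": [], "tags": []}'),
               class = "tpk_schema_error")  # missing fields
  bad <- '{"nodes": [[1,2]], "tags": ["X:visible"], "edges": [], "transitions": []}'
  expect_error(parseRawJson(bad), class = "tpk_schema_error")
  oob <- '{"nodes": [[1,2]], "tags": ["E:visible"], "edges": [[0,5]], "transitions": []}'
  expect_error(parseRawJson(oob), class = "tpk_schema_error")
  dup <- jsonlite::toJSON(list(
    nodes = list(c(1, 2), c(3, 4), c(5, 6)),
    tags = list("E:visible", "H:visible", "E:visible"),
    edges = list(c(0, 1), c(1, 2)), transitions = list()
  ), auto_unbox = TRUE)
  expect_error(parseRawJson(as.character(dup)), class = "tpk_schema_error")
})

test_that("serialization round trip is exact and idempotent", {
  set.seed(41)
  for (s in 1:25) {
    scn <- genScene(SceneConfig(seed = 500L + s))
    txt1 <- serializeRawJson(scn$annotation)
    fr2 <- parseRawJson(txt1, width = 960, height = 540)
    txt2 <- serializeRawJson(fr2)
    expect_identical(txt1, txt2)  # byte-identical double round trip
    # structural equality of the re-parsed frame
    expect_equal(length(poses(fr2)), length(poses(scn$annotation)))
    for (k in seq_along(poses(fr2))) {
      a <- poses(scn$annotation)[[k]]; b <- poses(fr2)[[k]]
      for (nm in c("entry", "hinge", "tip1", "tip2")) {
        expect_equal(kpX(slot(b, nm)), kpX(slot(a, nm)), tolerance = 1e-9)
        expect_equal(kpY(slot(b, nm)), kpY(slot(a, nm)), tolerance = 1e-9)
        expect_identical(kpTag(slot(b, nm)), kpTag(slot(a, nm)))
      }
      expect_equal(length(transitions(b)), length(transitions(a)))
      expect_identical(b@transitionEdges, a@transitionEdges)
    }
  }
})

test_that("occluded out-of-frame coordinates survive serialization", {
  p <- ToolPose(
    entry = Keypoint(-50, 200, "entry", "occluded"),
    hinge = Keypoint(-10.25, 220.5, "hinge", "occluded"),
    tip1 = Keypoint(100, 250, "tip1", "visible"),
    transitions = list(Keypoint(20, 235, "transition", "visible")),
    transitionEdges = "hinge-tip1",
    instanceId = 1L
  )
  fr <- FrameAnnotation(poses = list(p))
  fr2 <- parseRawJson(serializeRawJson(fr))
  expect_equal(kpX(entryPoint(poses(fr2)[[1]])), -50)
  expect_equal(kpY(hingePoint(poses(fr2)[[1]])), 220.5)
  expect_identical(kpTag(entryPoint(poses(fr2)[[1]])), "occluded")
  expect_identical(poses(fr2)[[1]]@transitionEdges, "hinge-tip1")
  # occluded points outside the frame are legal
  expect_equal(validatePose(p, 960, 540), character(0))
})

test_that("an empty frame serializes to a valid empty document", {
  fr <- FrameAnnotation(poses = list())
  fr2 <- parseRawJson(serializeRawJson(fr))
  expect_length(poses(fr2), 0)
})

test_that("unknown top-level fields are preserved opaquely", {
  doc <- jsonlite::toJSON(list(
    nodes = list(c(700, 20), c(500, 250), c(460, 330), c(545, 335)),
    tags = list("E:visible", "H:visible", "T1:visible", "T2:visible"),
    edges = list(c(0, 1), c(1, 2), c(1, 3)),
    transitions = list(),
    annotator = "A2", review_round = 2L
  ), auto_unbox = TRUE)
  fr <- parseRawJson(as.character(doc))
  expect_equal(fr@extra$annotator, "A2")
  txt <- serializeRawJson(fr)
  expect_match(txt, "\"annotator\":\"A2\"", fixed = TRUE)
  expect_match(txt, "\"review_round\":2", fixed = TRUE)
})

test_that("protocol violations are reported by rule and keypoint", {
  # visible out of bounds
  p <- ToolPose(entry = Keypoint(10, 10, "entry"),
                hinge = Keypoint(20, 20, "hinge"),
                tip1 = Keypoint(1000, 300, "tip1"),
                instanceId = 1L)
  v <- validatePose(p, 960, 540)
  expect_length(v, 1)
  expect_match(v, "visible out of bounds.*tip1")

  # rigid pose (tip2 missing) is clean
  rigid <- ToolPose(entry = Keypoint(700, 20, "entry"),
                    hinge = Keypoint(500, 250, "hinge"),
                    tip1 = Keypoint(460, 330, "tip1"),
                    instanceId = 1L)
  expect_equal(validatePose(rigid, 960, 540), character(0))

  # fully missing pose
  empty <- ToolPose(instanceId = 1L)
  expect_match(validatePose(empty, 960, 540), "empty pose", all = FALSE)

  # transition on an edge whose endpoints are both visible
  p2 <- visiblePose()
  p2@transitions <- list(Keypoint(600, 100, "transition", "visible"))
  p2@transitionEdges <- "entry-hinge"
  expect_match(validatePose(p2, 960, 540), "transition placement",
               all = FALSE)
})

test_that("all six protocol scenarios are constructible and validate cleanly", {
  scens <- c("art_all_visible", "art_occluded", "art_closed",
             "art_shaft_only", "rigid_all_visible", "rigid_shaft_only")
  for (sc in scens) {
    wts <- stats::setNames(as.numeric(scens == sc), scens)
    cfg <- SceneConfig(nToolsRange = c(1L, 1L),
                       articulatedFraction = as.numeric(startsWith(sc, "art")),
                       scenarioWeights = wts, seed = 99L)
    scn <- genScene(cfg)
    expect_identical(scn$scenarios, sc)
    expect_equal(nrow(validateFrame(scn$annotation)), 0)
    tags <- vapply(poseSlots <- list(
      entry = entryPoint(poses(scn$annotation)[[1]]),
      hinge = hingePoint(poses(scn$annotation)[[1]]),
      tip1 = tipPoints(poses(scn$annotation)[[1]])[[1]],
      tip2 = tipPoints(poses(scn$annotation)[[1]])[[2]]), kpTag, character(1))
    if (sc %in% c("art_closed", "rigid_all_visible"))
      expect_identical(unname(tags["tip2"]), "missing")
    if (endsWith(sc, "shaft_only"))
      expect_identical(unname(tags[c("tip1", "tip2")]),
                       c("missing", "missing"))
  }
})

test_that("every synthetic pose validates cleanly over many seeded draws", {
  nViol <- 0L
  for (s in 1:1000) {
    scn <- genScene(SceneConfig(seed = s))
    nViol <- nViol + nrow(validateFrame(scn$annotation))
  }
  expect_identical(nViol, 0L)
})
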