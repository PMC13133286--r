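# Shared fixture builders; everything is generated in code.

# A fully visible articulated pose well inside a 960 x 540 frame.
visiblePose <- function(instanceId = 1L) {
  ToolPose(
    entry = Keypoint(700, 20, "entry"),
    hinge = Keypoint(500, 250, "hinge"),
    tip1  = Keypoint(460, 330, "tip1"),
    tip2  = Keypoint(545, 335, "tip2"),
    instanceId = instanceId
  )
}

# Ground truth + noisy detections for a batch of synthetic scenes, as the
# package containers.  One scene per image id.
simulateBatch <- function(nScenes, baseSeed, noiseSd = 6, dropProb = 0,
                          swapProb = 0, config = SceneConfig()) {
  frames <- vector("list", nScenes)
  dets <- list()
  for (i in seq_len(nScenes)) {
    scn <- genScene(config, seed = baseSeed + i, frameId = sprintf("f%03d", i))
    frames[[i]] <- scn$annotation
    dets <- c(dets, perturbPredictions(
      scn$annotation, noiseSd = noiseSd, dropProb = dropProb,
      swapProb = swapProb, seed = 10000L + baseSeed + i, imageId = i))
  }
  list(gt = framesToCocoDataset(frames), dets = dets, frames = frames)
}

# A 12-vector of triplets from rows (x, y, v) given as a 4x3 matrix.
tripletVec <- function(...) as.numeric(t(matrix(c(...), ncol = 3, byrow = TRUE)))
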