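#' @include masks.R
NULL

#' Construct a synthetic-scene configuration
#'
#' Defaults emulate the downsampled endoscopic frame: 960 x 540 pixels with
#' a centred circular content area of radius 260 px, one to three instruments
#' per frame, two thirds of them articulated, visibility scenarios drawn
#' uniformly over the six protocol cases (four articulated, two rigid) and a
#' 12 px rendered shaft.
#'
#' @param width,height frame dimensions in pixels.
#' @param fovCenter,fovRadius circular content area (pixels).
#' @param nToolsRange integer (min, max) instruments per frame.
#' @param articulatedFraction probability of an articulated tool.
#' @param scenarioWeights named non-negative weights over
#'   \code{art_all_visible}, \code{art_occluded}, \code{art_closed},
#'   \code{art_shaft_only}, \code{rigid_all_visible},
#'   \code{rigid_shaft_only}; renormalised within each tool type.
#' @param shaftThickness rendered shaft thickness in pixels.
#' @param seed integer generator seed (\code{NA} = use the current stream).
#' @return A \code{\linkS4class{SceneConfig}}.
#' @export
SceneConfig <- function(width = 960, height = 540,
                        fovCenter = c(width / 2, height / 2),
                        fovRadius = min(width, height) / 2 - 10,
                        nToolsRange = c(1L, 3L),
                        articulatedFraction = 2 / 3,
                        scenarioWeights = stats::setNames(
                          rep(1, 6), sceneScenarios()),
                        shaftThickness = 12, seed = NA_integer_) {
  new("SceneConfig", width = as.numeric(width), height = as.numeric(height),
      fovCenter = as.numeric(fovCenter), fovRadius = as.numeric(fovRadius),
      nToolsRange = as.integer(nToolsRange),
      articulatedFraction = as.numeric(articulatedFraction),
      scenarioWeights = scenarioWeights[sceneScenarios()],
      shaftThickness = as.numeric(shaftThickness),
      seed = as.integer(seed))
}

#' @export
setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig %g x %g, fov r=%g at (%g, %g), %d-%d tool(s), seed %s\n",
    object@width, object@height, object@fovRadius,
    object@fovCenter[1], object@fovCenter[2],
    object@nToolsRange[1], object@nToolsRange[2],
    ifelse(is.na(object@seed), "<stream>", object@seed)))
})

## Paint a thick segment (capsule of radius r around a--b) into `labels`
## with value `id`, restricted to the capsule's bounding window.
paintCapsule <- function(labels, a, b, r, id) {
  h <- nrow(labels); w <- ncol(labels)
  r0 <- max(1L, floor(min(a[2], b[2]) - r)); r1 <- min(h, ceiling(max(a[2], b[2]) + r) + 1L)
  c0 <- max(1L, floor(min(a[1], b[1]) - r)); c1 <- min(w, ceiling(max(a[1], b[1]) + r) + 1L)
  if (r0 > r1 || c0 > c1) return(labels)
  px <- (c0:c1) - 0.5; py <- (r0:r1) - 0.5
  ab <- b - a; len2 <- sum(ab^2)
  X <- matrix(px, nrow = length(py), ncol = length(px), byrow = TRUE)
  Y <- matrix(py, nrow = length(py), ncol = length(px))
  t <- if (len2 > 0) ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2]) / len2 else 0
  t <- pmin(pmax(t, 0), 1)
  d2 <- (X - (a[1] + t * ab[1]))^2 + (Y - (a[2] + t * ab[2]))^2
  sub <- labels[r0:r1, c0:c1, drop = FALSE]
  sub[d2 <= r^2] <- id
  labels[r0:r1, c0:c1] <- sub
  labels
}

sampleScenario <- function(config) {
  art <- stats::runif(1) < config@articulatedFraction
  pool <- if (art) sceneScenarios()[1:4] else sceneScenarios()[5:6]
  wts <- config@scenarioWeights[pool]
  if (sum(wts) <= 0) wts <- rep(1, length(pool))
  sample(pool, 1, prob = wts)
}

genTool <- function(config, instanceId) {
  W <- config@width; H <- config@height
  ctr <- config@fovCenter; R <- config@fovRadius
  pad <- 3
  inFrame <- function(p) p[1] >= pad && p[1] < W - pad &&
    p[2] >= pad && p[2] < H - pad
  scenario <- sampleScenario(config)
  for (attempt in 1:200) {
    theta <- stats::runif(1, 0, 2 * pi)
    entry <- ctr + R * c(cos(theta), sin(theta))
    ang <- stats::runif(1, 0, 2 * pi)
    target <- ctr + 0.5 * R * sqrt(stats::runif(1)) * c(cos(ang), sin(ang))
    dir <- unitVec(target - entry)
    shaftLen <- stats::runif(1, 0.45 * R, 1.1 * R)
    hinge <- entry + shaftLen * dir
    tipLen <- stats::runif(1, 40, 90)
    alpha <- stats::runif(1, 0.08, 0.45)
    closed <- scenario %in% c("art_closed", "rigid_all_visible",
                              "rigid_shaft_only")
    tip1 <- if (closed) hinge + tipLen * dir
            else hinge + tipLen * rot2(dir, alpha)
    tip2 <- hinge + tipLen * rot2(dir, -alpha)
    if (inFrame(entry) && inFrame(hinge) && inFrame(tip1) && inFrame(tip2))
      break
    if (attempt == 200)
      stop("unsatisfiable scene geometry after bounded retries")
  }
  tags <- c(entry = "visible", hinge = "visible",
            tip1 = "visible", tip2 = "visible")
  if (scenario == "art_occluded") {
    occ <- sample(c("hinge", "tip1", "tip2", "tips"), 1)
    tags[if (occ == "tips") c("tip1", "tip2") else occ] <- "occluded"
  } else if (scenario %in% c("art_closed", "rigid_all_visible")) {
    tags["tip2"] <- "missing"
  } else if (scenario %in% c("art_shaft_only", "rigid_shaft_only")) {
    tags[c("tip1", "tip2")] <- "missing"
  }
  coords <- list(entry = entry, hinge = hinge, tip1 = tip1, tip2 = tip2)
  mk <- function(nm) {
    if (tags[[nm]] == "missing") missingKeypoint(nm)
    else Keypoint(coords[[nm]][1], coords[[nm]][2], nm, tags[[nm]])
  }
  # transition points on edges with a visible near end and an occluded far end
  edgeEnds <- list("entry-hinge" = c("entry", "hinge"),
                   "hinge-tip1" = c("hinge", "tip1"),
                   "hinge-tip2" = c("hinge", "tip2"))
  trans <- list(); transEdge <- character()
  for (edge in names(edgeEnds)) {
    ends <- edgeEnds[[edge]]
    et <- tags[ends]
    if (sum(et == "visible") != 1L || any(et == "missing")) next
    if (stats::runif(1) >= 0.5) next
    visEnd <- coords[[ends[et == "visible"]]]
    occEnd <- coords[[ends[et != "visible"]]]
    u <- stats::runif(1, 0.35, 0.8)
    p <- visEnd + u * (occEnd - visEnd)
    if (!inFrame(p)) next
    trans <- c(trans, Keypoint(p[1], p[2], "transition", "visible"))
    transEdge <- c(transEdge, edge)
  }
  list(
    pose = ToolPose(entry = mk("entry"), hinge = mk("hinge"),
                    tip1 = mk("tip1"), tip2 = mk("tip2"),
                    transitions = trans, transitionEdges = transEdge,
                    instanceId = instanceId),
    scenario = scenario,
    segments = {
      segs <- list(list(entry, hinge))
      if (tags[["tip1"]] == "visible") segs <- c(segs, list(list(hinge, tip1)))
      if (tags[["tip2"]] == "visible") segs <- c(segs, list(list(hinge, tip2)))
      segs
    }
  )
}

#' Generate one synthetic endoscopic scene
#'
#' Draws 1--3 instruments: the EntryPoint sits on the circular content
#' boundary, a straight shaft runs inward to the HingePoint, and one or two
#' tips extend beyond it (articulated tips opened by a sampled angle).
#' Visibility tags follow a sampled protocol scenario (rigid tools have a
#' missing second tip, shaft-only views have missing tips, occlusions get
#' optional transition points), and the paired instance mask renders each
#' instrument's visible segments as thick capsules, with later instruments
#' painted over earlier ones.  Deterministic given the seed; the mask
#' rendering consumes no random numbers, so annotations do not depend on it.
#'
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @param seed overrides \code{config@seed} when given.
#' @param frameId identifier of the generated frame.
#' @return list with elements \code{annotation}
#'   (\code{\linkS4class{FrameAnnotation}}), \code{mask}
#'   (\code{\linkS4class{InstanceMask}}) and \code{scenarios} (character
#'   vector of the per-tool visibility scenarios).
#' @export
genScene <- function(config = SceneConfig(), seed = config@seed,
                     frameId = "frame") {
  stopifnot(isTRUE(validObject(config, test = TRUE)))
  withSeed(seed, {
    r <- config@nToolsRange
    nTools <- if (r[1] == r[2]) r[1] else
      sample(seq(r[1], r[2]), 1)
    tools <- lapply(seq_len(nTools), function(k) genTool(config, k))
    labels <- matrix(0L, nrow = config@height, ncol = config@width)
    for (k in seq_along(tools))
      for (seg in tools[[k]]$segments)
        labels <- paintCapsule(labels, seg[[1]], seg[[2]],
                               config@shaftThickness / 2, k)
    list(
      annotation = FrameAnnotation(
        poses = lapply(tools, `[[`, "pose"), frameId = frameId,
        width = config@width, height = config@height),
      mask = InstanceMask(labels),
      scenarios = vapply(tools, `[[`, character(1), "scenario")
    )
  })
}

#' Perturb ground-truth poses into noisy scored detections
#'
#' Emulates a pose estimator for metric testing: every labelled keypoint is
#' jittered with isotropic Gaussian noise of standard deviation
#' \code{noiseSd}; with probability \code{swapProb} the two tip triplets are
#' exchanged; with probability \code{dropProb} the whole detection is
#' omitted; scores come from \code{scoreModel}.  The unit-variance noise is
#' drawn first and then scaled by \code{noiseSd}, so runs at the same seed
#' and increasing noise produce pointwise non-decreasing displacements
#' (useful for monotonicity studies).  Keypoints with visibility code 0 are
#' emitted as (0, 0, 0); each detection carries a keypoint-derived box
#' (20 px margin, clipped).
#'
#' @param frame a \code{\linkS4class{FrameAnnotation}} of ground truth.
#' @param noiseSd keypoint jitter standard deviation in pixels.
#' @param dropProb probability of omitting each detection.
#' @param swapProb probability of exchanging the predicted tips.
#' @param scoreModel function(n) returning n confidence scores.
#' @param seed integer seed (\code{NA} = current stream).
#' @param imageId image id stored on the detections.
#' @return list of \code{\linkS4class{ScoredDetection}}.
#' @export
perturbPredictions <- function(frame, noiseSd = 0, dropProb = 0,
                               swapProb = 0,
                               scoreModel = function(n)
                                 stats::runif(n, 0.5, 1),
                               seed = NA_integer_, imageId = 1L) {
  stopifnot(noiseSd >= 0, dropProb >= 0, dropProb <= 1,
            swapProb >= 0, swapProb <= 1)
  withSeed(seed, {
    dets <- list()
    for (pose in frame@poses) {
      z <- matrix(stats::rnorm(8), 4, 2)
      uDrop <- stats::runif(1)
      uSwap <- stats::runif(1)
      score <- scoreModel(1)
      if (uDrop < dropProb) next
      sl <- poseSlots(pose)
      v <- vapply(sl, visibilityCode, numeric(1),
                  width = frame@width, height = frame@height)
      kp <- numeric(12)
      for (i in seq_along(sl)) {
        if (v[i] > 0) {
          k <- sl[[i]]
          kp[3 * i - 2:0] <- c(k@x + noiseSd * z[i, 1],
                               k@y + noiseSd * z[i, 2], v[i])
        }
      }
      if (uSwap < swapProb)
        kp <- c(kp[1:6], kp[10:12], kp[7:9])
      tp <- matrix(kp, ncol = 3, byrow = TRUE)
      use <- tp[, 3] > 0
      if (!any(use)) next  # nothing labelled in frame: no detection
      x0 <- max(0, min(tp[use, 1]) - 20)
      y0 <- max(0, min(tp[use, 2]) - 20)
      x1 <- min(frame@width, max(tp[use, 1]) + 20)
      y1 <- min(frame@height, max(tp[use, 2]) + 20)
      dets[[length(dets) + 1L]] <- ScoredDetection(
        imageId, kp, score, bbox = BoundingBox(x0, y0, x1 - x0, y1 - y0))
    }
    dets
  })
}

#' Write a synthetic dataset directory tree
#'
#' Materialises the release layout
#' \code{<split>/<Surgery_type>/<Procedure_ID>/<Frame_ID>/} with, per frame,
#' a rendered placeholder image (\code{raw.png}: instrument instances in
#' flat colours over a dark circular field), the instance mask
#' (\code{instrument_instances.png}) and the pose annotation
#' (\code{raw.json}).  Training and Validation share two surgery types;
#' Testing adds a third, held-out type, mirroring the released split
#' structure.  Deterministic given the seed.
#'
#' @param root writable directory; must be empty or absent unless
#'   \code{force}.
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @param frames named integer vector: frames per split.
#' @param proceduresPerSplit procedures per surgery type within a split.
#' @param seed integer seed.
#' @param force overwrite a non-empty root.
#' @return Manifest: list with \code{root}, \code{seed} and a data.frame
#'   \code{frames} (split, surgery, procedure, frame, dir); also written to
#'   \code{<root>/manifest.json}.
#' @export
genDatasetTree <- function(root, config = SceneConfig(),
                           frames = c(Training = 4L, Validation = 2L,
                                      Testing = 4L),
                           proceduresPerSplit = 2L,
                           seed = NA_integer_, force = FALSE) {
  if (dir.exists(root) && length(dir(root, all.files = FALSE)) && !force)
    stop("refusing to write into non-empty directory: ", root)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  surgeries <- list(
    Training = c("Proctocolectomy", "Rectal_resection"),
    Validation = c("Proctocolectomy", "Rectal_resection"),
    Testing = c("Proctocolectomy", "Rectal_resection", "Sigmoid_resection")
  )
  withSeed(seed, {
    rows <- list()
    for (split in names(frames)) {
      n <- frames[[split]]
      surg <- surgeries[[split]]
      combos <- expand.grid(surgery = surg,
                            procedure = seq_len(proceduresPerSplit),
                            stringsAsFactors = FALSE)
      for (i in seq_len(n)) {
        cmb <- combos[(i - 1L) %% nrow(combos) + 1L, ]
        frameName <- sprintf("frame_%03d", i)
        dirPath <- file.path(root, split, cmb$surgery,
                             sprintf("%d_procedure", cmb$procedure),
                             frameName)
        dir.create(dirPath, recursive = TRUE, showWarnings = FALSE)
        scene <- genScene(config, seed = NA_integer_, frameId = frameName)
        writeMask(scene$mask, file.path(dirPath, "instrument_instances.png"))
        writeRawJson(scene$annotation, file.path(dirPath, "raw.json"))
        renderPlaceholder(scene$mask, config,
                          file.path(dirPath, "raw.png"))
        rows[[length(rows) + 1L]] <- data.frame(
          split = split, surgery = cmb$surgery,
          procedure = sprintf("%d_procedure", cmb$procedure),
          frame = frameName,
          dir = file.path(split, cmb$surgery,
                          sprintf("%d_procedure", cmb$procedure), frameName),
          stringsAsFactors = FALSE)
      }
    }
    manifest <- list(seed = if (is.na(seed)) NULL else seed,
                     frames = do.call(rbind, rows))
    jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    c(list(root = root), manifest)
  })
}

## Flat-colour render of the mask over a dark circular field; purely
## decorative (metrics never read it).
renderPlaceholder <- function(mask, config, path) {
  lab <- mask@labels
  h <- nrow(lab); w <- ncol(lab)
  px <- (seq_len(w)) - 0.5; py <- (seq_len(h)) - 0.5
  d2 <- outer((py - config@fovCenter[2])^2, (px - config@fovCenter[1])^2, `+`)
  base <- ifelse(d2 <= config@fovRadius^2, 0.35, 0.05)
  palette <- matrix(c(0.85, 0.35, 0.25,
                      0.30, 0.70, 0.85,
                      0.55, 0.80, 0.35,
                      0.90, 0.75, 0.30), ncol = 3, byrow = TRUE)
  img <- array(rep(base, 3), dim = c(h, w, 3))
  for (id in sort(setdiff(unique(as.vector(lab)), 0L))) {
    colr <- palette[(id - 1L) %% nrow(palette) + 1L, ]
    sel <- lab == id
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[sel] <- colr[ch]; img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
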