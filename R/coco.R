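#' @include bbox.R
NULL

slotOrder <- c("entry", "hinge", "tip1", "tip2")
categoryKeypointNames <- c("EntryPoint", "HingePoint", "Tip1", "Tip2")

#' Visibility code of one keypoint in the COCO-style export
#'
#' Maps the three-state visibility taxonomy onto the COCO v codes:
#' visible -> 2; occluded with both coordinates inside the frame -> 1;
#' occluded outside the frame -> 0; missing -> 0.  The frame test uses the
#' half-open convention \eqn{0 \le x < W}, \eqn{0 \le y < H}.
#'
#' @param kp a \code{\linkS4class{Keypoint}}.
#' @param width,height frame dimensions in pixels.
#' @return Integer 0, 1 or 2.
#' @export
visibilityCode <- function(kp, width = 960, height = 540) {
  switch(kp@tag,
    visible = 2,
    occluded = if (kp@x >= 0 && kp@x < width && kp@y >= 0 && kp@y < height)
      1 else 0,
    missing = 0
  )
}

#' Construct a CocoAnnotation
#'
#' @param imageId,id,categoryId integer identifiers.
#' @param keypoints numeric vector of 12 values (4 x-y-v triplets in the order
#'   EntryPoint, HingePoint, Tip1, Tip2).
#' @param bbox a \code{\linkS4class{BoundingBox}}.
#' @param area box area in the diagonal-squared convention
#'   (\eqn{w^2 + h^2}); computed from \code{bbox} when omitted.
#' @return A \code{\linkS4class{CocoAnnotation}}.
#' @export
CocoAnnotation <- function(imageId, id, keypoints, bbox,
                           area = bbox@w^2 + bbox@h^2, categoryId = 1L) {
  kp <- as.numeric(keypoints)
  v <- kp[seq(3, 12, by = 3)]
  if (!all(v %in% 0:2)) schemaError("visibility code outside {0, 1, 2}")
  new("CocoAnnotation", imageId = as.integer(imageId), id = as.integer(id),
      keypoints = kp, numKeypoints = as.integer(sum(v > 0)),
      bbox = bbox, area = as.numeric(area),
      categoryId = as.integer(categoryId))
}

#' Convert one pose to a COCO-style annotation
#'
#' Keypoints are serialized in the canonical slot order EntryPoint,
#' HingePoint, Tip1, Tip2; keypoints with visibility code 0 are written as
#' the (0, 0, 0) placeholder.  The stored box is the margin-expanded, clipped
#' keypoint box and \code{area} is its squared diagonal \eqn{w^2 + h^2}.
#' Transition points are not exported.
#'
#' @param pose a \code{\linkS4class{ToolPose}} with at least one keypoint of
#'   visibility code > 0.
#' @param imageId,annId integer identifiers for the image and annotation.
#' @param width,height frame dimensions in pixels.
#' @param margin bounding-box margin in pixels.
#' @return A \code{\linkS4class{CocoAnnotation}}.
#' @export
poseToCoco <- function(pose, imageId = 1L, annId = 1L,
                       width = 960, height = 540, margin = 20) {
  sl <- poseSlots(pose)
  v <- vapply(sl, visibilityCode, numeric(1), width = width, height = height)
  if (!any(v > 0))
    schemaError("cannot convert a pose with no labelled keypoint")
  kp <- numeric(12)
  for (i in seq_along(slotOrder)) {
    k <- sl[[slotOrder[i]]]
    kp[3 * i - 2:0] <- if (v[i] > 0) c(k@x, k@y, v[i]) else c(0, 0, 0)
  }
  CocoAnnotation(imageId = imageId, id = annId, keypoints = kp,
                 bbox = keypointBbox(pose, width, height, margin))
}

#' Recover a pose from a COCO-style annotation (lossy inverse)
#'
#' v = 2 becomes visible, v = 1 occluded, v = 0 missing; transition points
#' cannot be recovered.  \code{poseToCoco(cocoToPose(a))} reproduces the
#' keypoint triplets, \code{numKeypoints} and visibility codes exactly for
#' any protocol-conforming annotation.
#'
#' @param ann a \code{\linkS4class{CocoAnnotation}}.
#' @param instanceId instance id for the recovered pose (default the
#'   annotation id).
#' @return A \code{\linkS4class{ToolPose}}.
#' @export
cocoToPose <- function(ann, instanceId = ann@id) {
  kp <- ann@keypoints
  mk <- function(i, role) {
    x <- kp[3 * i - 2]; y <- kp[3 * i - 1]; v <- kp[3 * i]
    if (!v %in% 0:2) schemaError("visibility code outside {0, 1, 2}")
    Keypoint(x, y, role,
             tag = c("missing", "occluded", "visible")[v + 1])
  }
  ToolPose(entry = mk(1, "entry"), hinge = mk(2, "hinge"),
           tip1 = mk(3, "tip1"), tip2 = mk(4, "tip2"),
           instanceId = instanceId)
}

#' Assemble a CocoDataset from frame annotations
#'
#' @param frames list of \code{\linkS4class{FrameAnnotation}} objects.
#' @param fileNames image file names recorded in the \code{images} table
#'   (defaults to \code{<frameId>/raw.png}).
#' @param margin bounding-box margin in pixels.
#' @return A \code{\linkS4class{CocoDataset}} with a single instrument
#'   category.
#' @export
framesToCocoDataset <- function(frames,
                                fileNames = vapply(frames, function(f)
                                  file.path(frameId(f), "raw.png"),
                                  character(1)),
                                margin = 20) {
  images <- data.frame(
    id = seq_along(frames),
    file_name = fileNames,
    width = vapply(frames, function(f) f@width, numeric(1)),
    height = vapply(frames, function(f) f@height, numeric(1)),
    stringsAsFactors = FALSE
  )
  anns <- list(); annId <- 0L
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    for (pose in f@poses) {
      annId <- annId + 1L
      anns[[annId]] <- poseToCoco(pose, imageId = i, annId = annId,
                                  width = f@width, height = f@height,
                                  margin = margin)
    }
  }
  new("CocoDataset", images = images, annotations = anns,
      categories = list(instrumentCategory()))
}

instrumentCategory <- function() {
  list(id = 1L, name = "surgical_instrument",
       supercategory = "instrument",
       keypoints = as.list(categoryKeypointNames),
       skeleton = list(c(1L, 2L), c(2L, 3L), c(2L, 4L)))
}

#' @rdname accessors
#' @export
setMethod("annotations", "CocoDataset", function(x) x@annotations)
#' @rdname accessors
#' @export
setMethod("images", "CocoDataset", function(x) x@images)
#' @rdname accessors
#' @export
setMethod("keypointTriplets", "CocoAnnotation",
          function(x) matrix(x@keypoints, ncol = 3, byrow = TRUE,
                             dimnames = list(slotOrder, c("x", "y", "v"))))
#' @rdname accessors
#' @export
setMethod("keypointTriplets", "ScoredDetection",
          function(x) matrix(x@keypoints, ncol = 3, byrow = TRUE,
                             dimnames = list(slotOrder, c("x", "y", "v"))))
#' @rdname accessors
#' @export
setMethod("bboxVector", "CocoAnnotation", function(x) bboxVector(x@bbox))

#' @export
setMethod("show", "CocoDataset", function(object) {
  cat(sprintf("CocoDataset: %d image(s), %d annotation(s), %d category\n",
              nrow(object@images), length(object@annotations),
              length(object@categories)))
})

## COCO JSON I/O --------------------------------------------------------------

#' Read / write the COCO-style keypoint JSON
#'
#' @param path file path of the dataset JSON.
#' @param dataset a \code{\linkS4class{CocoDataset}} (for writing).
#' @return \code{readCocoDataset}: a \code{CocoDataset};
#'   \code{writeCocoDataset}: the path, invisibly.
#' @export
readCocoDataset <- function(path) {
  if (!file.exists(path)) parseError("no such file: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) parseError("malformed JSON: %s",
                                                 conditionMessage(e)))
  for (f in c("images", "annotations", "categories"))
    if (is.null(doc[[f]])) schemaError("missing COCO field '%s'", f)
  images <- do.call(rbind, lapply(doc$images, function(im) data.frame(
    id = as.integer(im$id), file_name = as.character(im$file_name),
    width = as.numeric(im$width), height = as.numeric(im$height),
    stringsAsFactors = FALSE
  )))
  if (is.null(images))
    images <- data.frame(id = integer(), file_name = character(),
                         width = numeric(), height = numeric())
  anns <- lapply(doc$annotations, function(a) {
    bb <- as.numeric(unlist(a$bbox))
    CocoAnnotation(
      imageId = a$image_id, id = a$id,
      keypoints = as.numeric(unlist(a$keypoints)),
      bbox = BoundingBox(bb[1], bb[2], bb[3], bb[4]),
      area = if (is.null(a$area)) bb[3]^2 + bb[4]^2 else as.numeric(a$area),
      categoryId = if (is.null(a$category_id)) 1L else a$category_id
    )
  })
  new("CocoDataset", images = images, annotations = anns,
      categories = if (length(doc$categories)) doc$categories
                   else list(instrumentCategory()))
}

#' @rdname readCocoDataset
#' @export
writeCocoDataset <- function(dataset, path) {
  doc <- list(
    images = lapply(seq_len(nrow(dataset@images)), function(i) {
      im <- dataset@images[i, ]
      list(id = im$id, file_name = im$file_name,
           width = im$width, height = im$height)
    }),
    annotations = lapply(dataset@annotations, function(a) list(
      id = a@id, image_id = a@imageId, category_id = a@categoryId,
      keypoints = as.list(a@keypoints), num_keypoints = a@numKeypoints,
      bbox = as.list(unname(bboxVector(a@bbox))), area = a@area,
      iscrowd = 0L
    )),
    categories = dataset@categories
  )
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           digits = NA)), path)
  invisible(path)
}

#' Construct a ScoredDetection
#'
#' @param imageId integer image identifier.
#' @param keypoints numeric vector of 12 values (4 triplets).
#' @param score confidence score.
#' @param bbox optional \code{\linkS4class{BoundingBox}}.
#' @return A \code{\linkS4class{ScoredDetection}}.
#' @export
ScoredDetection <- function(imageId, keypoints, score, bbox = NULL) {
  new("ScoredDetection", imageId = as.integer(imageId),
      keypoints = as.numeric(keypoints), score = as.numeric(score),
      bbox = bbox)
}

#' Read / write prediction files in COCO results format
#'
#' A results file is a JSON array of objects with \code{image_id},
#' \code{category_id}, \code{keypoints} (12 numbers) and \code{score}, plus
#' an optional \code{bbox}.
#'
#' @param path file path.
#' @param detections list of \code{\linkS4class{ScoredDetection}} (for
#'   writing).
#' @return \code{readDetections}: list of \code{ScoredDetection};
#'   \code{writeDetections}: the path, invisibly.
#' @export
readDetections <- function(path) {
  if (!file.exists(path)) parseError("no such file: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) parseError("malformed JSON: %s",
                                                 conditionMessage(e)))
  lapply(doc, function(d) {
    bb <- if (is.null(d$bbox)) NULL else {
      b <- as.numeric(unlist(d$bbox)); BoundingBox(b[1], b[2], b[3], b[4])
    }
    ScoredDetection(d$image_id, as.numeric(unlist(d$keypoints)),
                    d$score, bbox = bb)
  })
}

#' @rdname readDetections
#' @export
writeDetections <- function(detections, path) {
  doc <- lapply(detections, function(d) {
    out <- list(image_id = d@imageId, category_id = 1L,
                keypoints = as.list(d@keypoints), score = d@score)
    if (!is.null(d@bbox))
      out$bbox <- as.list(unname(bboxVector(d@bbox)))
    out
  })
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           digits = NA)), path)
  invisible(path)
}
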