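#' @import methods
NULL

## Controlled vocabularies ---------------------------------------------------

#' Visibility states of a skeletal keypoint
#'
#' Every keypoint of a tool skeleton carries one of three visibility states:
#' \describe{
#'   \item{visible}{the landmark is directly seen in the image;}
#'   \item{occluded}{the landmark is hidden (by tissue, by the circular
#'     field-of-view vignette, or lying outside the frame) but its position
#'     can be inferred from the mostly rigid tool geometry;}
#'   \item{missing}{the landmark is physically absent (e.g. the second tip of
#'     a rigid probe) or cannot be inferred at all.}
#' }
#' @export
visibilityStates <- function() c("visible", "occluded", "missing")

#' Canonical keypoint roles of the four-slot tool skeleton
#'
#' The skeleton has four canonical slots, chained as
#' EntryPoint--HingePoint--Tip1 and HingePoint--Tip2, plus free-floating
#' transition points marking the farthest visible position along an edge
#' whose far endpoint is not visible.
#' @export
keypointRoles <- function() c("entry", "hinge", "tip1", "tip2", "transition")

## Named chain edges; an edge exists when both endpoints are non-missing.
chainEdges <- function() c("entry-hinge", "hinge-tip1", "hinge-tip2")

## Keypoint -------------------------------------------------------------------

#' Keypoint: one skeletal landmark
#'
#' A landmark with continuous pixel coordinates (0-based, origin at the
#' top-left corner of the top-left pixel), a semantic role and a visibility
#' state.  Coordinates of a \code{missing} keypoint are a (0, 0) sentinel and
#' must never enter arithmetic; exclusion is always by tag, never by value.
#' Occluded keypoints may lie outside the frame (annotation padding area).
#'
#' @slot x,y numeric scalar pixel coordinates.
#' @slot role one of \code{keypointRoles()}.
#' @slot tag one of \code{visibilityStates()}.
#' @export
setClass("Keypoint", representation(
  x = "numeric", y = "numeric", role = "character", tag = "character"
))

setValidity("Keypoint", function(object) {
  msg <- character()
  if (length(object@x) != 1L || length(object@y) != 1L)
    msg <- c(msg, "x and y must be scalars")
  if (!object@role %in% keypointRoles())
    msg <- c(msg, sprintf("unknown role '%s'", object@role))
  if (!object@tag %in% visibilityStates())
    msg <- c(msg, sprintf("unknown visibility tag '%s'", object@tag))
  if (object@tag != "missing" && (!is.finite(object@x) || !is.finite(object@y)))
    msg <- c(msg, "non-missing keypoints need finite coordinates")
  if (length(msg)) msg else TRUE
})

## ToolPose -------------------------------------------------------------------

#' ToolPose: the four-slot skeleton of one instrument instance
#'
#' Holds the four canonical keypoint slots plus any transition points, each
#' transition attached to exactly one chain edge.  At least one of the four
#' slots must be non-missing for the pose to be meaningful; this and the
#' in-bounds rules for visible keypoints are protocol checks reported by
#' \code{\link{validatePose}} rather than hard slot invariants, so that
#' nonconforming files can be parsed and diagnosed.
#'
#' @slot entry,hinge,tip1,tip2 \code{Keypoint} objects in their canonical roles.
#' @slot transitions list of \code{Keypoint} objects with role
#'   \code{"transition"}.
#' @slot transitionEdges character vector parallel to \code{transitions},
#'   naming the chain edge each transition lies on
#'   (\code{"entry-hinge"}, \code{"hinge-tip1"} or \code{"hinge-tip2"}).
#' @slot instanceId integer instance identifier, unique within a frame.
#' @export
setClass("ToolPose", representation(
  entry = "Keypoint", hinge = "Keypoint", tip1 = "Keypoint", tip2 = "Keypoint",
  transitions = "list", transitionEdges = "character", instanceId = "integer"
))

setValidity("ToolPose", function(object) {
  msg <- character()
  for (nm in c("entry", "hinge", "tip1", "tip2")) {
    kp <- slot(object, nm)
    want <- nm
    if (kp@role != want)
      msg <- c(msg, sprintf("slot '%s' holds a keypoint with role '%s'", nm, kp@role))
  }
  if (length(object@transitions) != length(object@transitionEdges))
    msg <- c(msg, "transitions and transitionEdges must be parallel")
  ok <- vapply(object@transitions, function(t)
    is(t, "Keypoint") && t@role == "transition", logical(1))
  if (!all(ok)) msg <- c(msg, "transitions must be Keypoints with role 'transition'")
  bad <- setdiff(object@transitionEdges, chainEdges())
  if (length(bad))
    msg <- c(msg, sprintf("unknown transition edge '%s'", bad[1]))
  if (length(object@instanceId) != 1L || is.na(object@instanceId))
    msg <- c(msg, "instanceId must be a single non-missing integer")
  if (length(msg)) msg else TRUE
})

## FrameAnnotation ------------------------------------------------------------

#' FrameAnnotation: all tool poses of one endoscopic frame
#'
#' @slot frameId frame identifier string.
#' @slot width,height frame dimensions in pixels (default 960 x 540).
#' @slot poses list of \code{ToolPose}; instance ids unique within the frame.
#' @slot maskPath optional path to the paired instance mask PNG
#'   (\code{NA_character_} when absent).
#' @slot extra named list of unknown fields of the on-disk record, preserved
#'   opaquely across a parse/serialize round trip.
#' @export
setClass("FrameAnnotation", representation(
  frameId = "character", width = "numeric", height = "numeric",
  poses = "list", maskPath = "character", extra = "list"
))

setValidity("FrameAnnotation", function(object) {
  msg <- character()
  if (object@width <= 0 || object@height <= 0)
    msg <- c(msg, "frame dimensions must be positive")
  if (!all(vapply(object@poses, is, logical(1), "ToolPose")))
    msg <- c(msg, "poses must be ToolPose objects")
  ids <- vapply(object@poses, function(p) p@instanceId, integer(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "pose instance ids must be unique within a frame")
  if (length(msg)) msg else TRUE
})

## BoundingBox ----------------------------------------------------------------

#' BoundingBox: axis-aligned box in [xmin, ymin, w, h] form
#'
#' @slot xmin,ymin top-left corner in pixels.
#' @slot w,h non-negative width and height in pixels.
#' @export
setClass("BoundingBox", representation(
  xmin = "numeric", ymin = "numeric", w = "numeric", h = "numeric"
))

setValidity("BoundingBox", function(object) {
  if (object@w < 0 || object@h < 0) "w and h must be non-negative" else TRUE
})

setClassUnion("BoundingBoxOrNULL", c("BoundingBox", "NULL"))

## COCO-style containers ------------------------------------------------------

#' CocoAnnotation: one instrument instance in the COCO-style export
#'
#' Keypoints are a flat vector of 4 (x, y, v) triplets in the fixed slot order
#' EntryPoint, HingePoint, Tip1, Tip2, with visibility codes
#' v = 2 (annotated and visible), v = 1 (annotated and occluded, inside the
#' frame) and v = 0 (not annotated: missing, or occluded outside the frame).
#' \code{numKeypoints} counts triplets with v > 0.  \code{area} is the square
#' of the box diagonal, \eqn{w^2 + h^2} — deliberately not the conventional
#' COCO \eqn{w \cdot h}; the evaluator derives its scale from the box
#' dimensions, not from this field's conventional meaning.
#'
#' @slot imageId,id,categoryId integer identifiers.
#' @slot keypoints numeric vector of length 12.
#' @slot numKeypoints integer count of labelled keypoints.
#' @slot bbox \code{BoundingBox} (margin-expanded, clipped).
#' @slot area numeric, \eqn{w^2 + h^2} of the box.
#' @export
setClass("CocoAnnotation", representation(
  imageId = "integer", id = "integer", keypoints = "numeric",
  numKeypoints = "integer", bbox = "BoundingBox", area = "numeric",
  categoryId = "integer"
))

setValidity("CocoAnnotation", function(object) {
  msg <- character()
  if (length(object@keypoints) != 12L)
    msg <- c(msg, "keypoints must hold 4 (x, y, v) triplets")
  v <- object@keypoints[seq(3, 12, by = 3)]
  if (!all(v %in% 0:2))
    msg <- c(msg, "visibility codes must be in {0, 1, 2}")
  if (length(object@numKeypoints) == 1L && object@numKeypoints != sum(v > 0))
    msg <- c(msg, "numKeypoints must equal the number of triplets with v > 0")
  if (length(msg)) msg else TRUE
})

#' CocoDataset: images/annotations/categories containers
#'
#' @slot images data.frame with columns \code{id}, \code{file_name},
#'   \code{width}, \code{height}.
#' @slot annotations list of \code{CocoAnnotation}.
#' @slot categories single-entry list describing the one instrument category,
#'   including its keypoint names and skeleton edges.
#' @export
setClass("CocoDataset", representation(
  images = "data.frame", annotations = "list", categories = "list"
))

setValidity("CocoDataset", function(object) {
  msg <- character()
  need <- c("id", "file_name", "width", "height")
  if (!all(need %in% names(object@images)))
    msg <- c(msg, "images must have columns id, file_name, width, height")
  if (!all(vapply(object@annotations, is, logical(1), "CocoAnnotation")))
    msg <- c(msg, "annotations must be CocoAnnotation objects")
  else {
    iid <- vapply(object@annotations, function(a) a@imageId, integer(1))
    if (length(iid) && !all(iid %in% object@images$id))
      msg <- c(msg, "every annotation imageId must resolve to an image")
    aid <- vapply(object@annotations, function(a) a@id, integer(1))
    if (anyDuplicated(aid)) msg <- c(msg, "annotation ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

## Metric parameter and result containers -------------------------------------

#' OksParams: parameters of the keypoint similarity metric
#'
#' @slot sigma per-keypoint scale-normalised standard deviation; a single
#'   conservative value of 0.107 is used for all four roles.
#' @slot kappa per-keypoint falloff constant, \eqn{\kappa_i = 2 \sigma_i}.
#' @slot oksThresholds similarity thresholds for AP/AR, 0.50 to 0.95 by 0.05.
#' @slot maxDetections per-image detection cap (default 20).
#' @slot tipSwap logical; evaluate against both tip orderings and keep the
#'   better value (default \code{TRUE}).
#' @export
setClass("OksParams", representation(
  sigma = "numeric", kappa = "numeric", oksThresholds = "numeric",
  maxDetections = "integer", tipSwap = "logical"
))

setValidity("OksParams", function(object) {
  msg <- character()
  if (length(object@sigma) != 4L || any(object@sigma <= 0))
    msg <- c(msg, "sigma must be 4 positive values")
  if (length(object@kappa) != 4L ||
      max(abs(object@kappa - 2 * object@sigma)) > 1e-12)
    msg <- c(msg, "kappa must equal 2 * sigma")
  th <- object@oksThresholds
  if (any(diff(th) <= 0) || any(th <= 0) || any(th >= 1))
    msg <- c(msg, "thresholds must be strictly increasing within (0, 1)")
  if (object@maxDetections < 1L)
    msg <- c(msg, "maxDetections must be positive")
  if (length(msg)) msg else TRUE
})

#' ScoredDetection: one predicted instrument pose with a confidence score
#'
#' Keypoint layout is identical to \code{\linkS4class{CocoAnnotation}}.
#' Predicted visibility codes are carried but never used by the metric.
#'
#' @slot imageId integer image identifier.
#' @slot keypoints numeric vector of length 12 (4 triplets).
#' @slot score finite confidence score.
#' @slot bbox optional \code{BoundingBox} for the box protocol.
#' @export
setClass("ScoredDetection", representation(
  imageId = "integer", keypoints = "numeric", score = "numeric",
  bbox = "BoundingBoxOrNULL"
))

setValidity("ScoredDetection", function(object) {
  msg <- character()
  if (length(object@keypoints) != 12L)
    msg <- c(msg, "keypoints must hold 4 (x, y, v) triplets")
  if (length(object@score) != 1L || !is.finite(object@score))
    msg <- c(msg, "score must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' EvalSummary: COCO-protocol AP/AR summary
#'
#' Headline fields are the mean over the threshold grid plus the two
#' conventional fixed thresholds 0.50 and 0.75, for both precision and
#' recall.  When the ground truth contains no evaluable instance all fields
#' carry the COCO sentinel -1.
#'
#' @slot protocol \code{"OKS"} or \code{"IoU"}.
#' @slot thresholds the similarity threshold grid.
#' @slot apMean,ap050,ap075,arMean,ar050,ar075 headline values.
#' @slot precision matrix (thresholds x 101 recall points) of interpolated
#'   precision.
#' @slot recall per-threshold maximal recall at the detection cap.
#' @slot recallGrid the 101-point recall grid 0, 0.01, ..., 1.
#' @export
setClass("EvalSummary", representation(
  protocol = "character", thresholds = "numeric",
  apMean = "numeric", ap050 = "numeric", ap075 = "numeric",
  arMean = "numeric", ar050 = "numeric", ar075 = "numeric",
  precision = "matrix", recall = "numeric", recallGrid = "numeric"
))

setValidity("EvalSummary", function(object) {
  vals <- c(object@apMean, object@ap050, object@ap075,
            object@arMean, object@ar050, object@ar075)
  # -1 is the COCO "undefined" sentinel for empty ground truth
  if (!all(vals == -1 | (vals >= 0 & vals <= 1)))
    return("summary values must lie in [0, 1] (or be the -1 sentinel)")
  TRUE
})

## InstanceMask ---------------------------------------------------------------

#' InstanceMask: pixel-wise instance labels of one frame
#'
#' @slot labels integer matrix indexed \code{[y + 1, x + 1]} (row-major from
#'   the top-left corner, matching the PNG raster); 0 = background, k > 0 =
#'   instance k.
#' @export
setClass("InstanceMask", representation(labels = "matrix"))

setValidity("InstanceMask", function(object) {
  msg <- character()
  if (!is.numeric(object@labels))
    msg <- c(msg, "labels must be a numeric/integer matrix")
  else if (any(object@labels < 0) || any(object@labels != round(object@labels)))
    msg <- c(msg, "labels must be non-negative integers")
  if (length(msg)) msg else TRUE
})

## SceneConfig ----------------------------------------------------------------

#' SceneConfig: parameters of the synthetic endoscopic scene generator
#'
#' @slot width,height frame dimensions in pixels.
#' @slot fovCenter,fovRadius centre and radius (pixels) of the circular
#'   informative content area.
#' @slot nToolsRange integer range (min, max) of instruments per frame.
#' @slot articulatedFraction probability that a tool is articulated.
#' @slot scenarioWeights named non-negative weights over the six visibility
#'   scenarios (four articulated, two rigid); renormalised within tool type.
#' @slot shaftThickness rendered shaft thickness in pixels.
#' @slot seed integer seed of the generator stream (\code{NA} = leave the
#'   global stream untouched).
#' @export
setClass("SceneConfig", representation(
  width = "numeric", height = "numeric",
  fovCenter = "numeric", fovRadius = "numeric",
  nToolsRange = "integer", articulatedFraction = "numeric",
  scenarioWeights = "numeric", shaftThickness = "numeric", seed = "integer"
))

sceneScenarios <- function() c(
  "art_all_visible", "art_occluded", "art_closed", "art_shaft_only",
  "rigid_all_visible", "rigid_shaft_only"
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@width <= 0 || object@height <= 0)
    msg <- c(msg, "frame dimensions must be positive")
  cx <- object@fovCenter[1]; cy <- object@fovCenter[2]
  if (object@fovRadius <= 0 ||
      cx + object@fovRadius < 0 || cx - object@fovRadius > object@width ||
      cy + object@fovRadius < 0 || cy - object@fovRadius > object@height)
    msg <- c(msg, "fov circle must intersect the frame")
  if (length(object@nToolsRange) != 2L || object@nToolsRange[1] < 0 ||
      object@nToolsRange[2] < object@nToolsRange[1])
    msg <- c(msg, "nToolsRange must be a non-decreasing (min, max) pair")
  if (object@articulatedFraction < 0 || object@articulatedFraction > 1)
    msg <- c(msg, "articulatedFraction must be a probability")
  w <- object@scenarioWeights
  if (!setequal(names(w), sceneScenarios()) || any(w < 0) || sum(w) <= 0)
    msg <- c(msg, "scenarioWeights must be non-negative over the six scenarios")
  if (object@shaftThickness <= 0)
    msg <- c(msg, "shaftThickness must be positive")
  if (length(msg)) msg else TRUE
})
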