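#' @include pose.R
NULL

#' Construct a BoundingBox
#'
#' @param xmin,ymin top-left corner in pixels.
#' @param w,h non-negative width and height in pixels.
#' @return A \code{\linkS4class{BoundingBox}}.
#' @export
BoundingBox <- function(xmin, ymin, w, h) {
  new("BoundingBox", xmin = as.numeric(xmin), ymin = as.numeric(ymin),
      w = as.numeric(w), h = as.numeric(h))
}

#' @rdname accessors
#' @export
setMethod("bboxVector", "BoundingBox",
          function(x) c(xmin = x@xmin, ymin = x@ymin, w = x@w, h = x@h))

#' @export
setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox [%g, %g, %g, %g]\n",
              object@xmin, object@ymin, object@w, object@h))
})

#' Keypoint-derived bounding box with margin and clipping
#'
#' The box is the axis-aligned extent of the keypoints with visibility code
#' v > 0 (visible, or occluded inside the frame), expanded by \code{margin}
#' pixels on all four sides; where the expanded box exceeds the frame, the
#' frame boundary is used as the limit.  Keypoints with v = 0 (missing, or
#' occluded outside the frame) never contribute.  Because tools are slender
#' and the raw keypoint extent collapses for axis-aligned poses, the margin
#' (default 20 px) keeps boxes usable for top-down detection.
#'
#' @param pose a \code{\linkS4class{ToolPose}}.
#' @param width,height frame dimensions in pixels.
#' @param margin margin in pixels added to each side before clipping.
#' @return A \code{\linkS4class{BoundingBox}}.
#' @examples
#' p <- ToolPose(
#'   entry = Keypoint(100, 200, "entry"),
#'   hinge = Keypoint(400, 250, "hinge"),
#'   tip1  = Keypoint(380, 300, "tip1"),
#'   instanceId = 1L
#' )
#' bboxVector(keypointBbox(p, 960, 540))  # [80, 180, 340, 140]
#' @export
keypointBbox <- function(pose, width = 960, height = 540, margin = 20) {
  sl <- poseSlots(pose)
  v <- vapply(sl, visibilityCode, numeric(1), width = width, height = height)
  use <- v > 0
  if (!any(use))
    schemaError("empty extent: no keypoint with visibility code > 0")
  xs <- vapply(sl[use], kpX, numeric(1))
  ys <- vapply(sl[use], kpY, numeric(1))
  x0 <- max(0, min(xs) - margin)
  y0 <- max(0, min(ys) - margin)
  x1 <- min(width, max(xs) + margin)
  y1 <- min(height, max(ys) + margin)
  BoundingBox(x0, y0, x1 - x0, y1 - y0)
}

#' Intersection over union of two boxes
#'
#' Standard IoU on areas \eqn{w \cdot h}; two zero-area boxes have IoU 0.
#'
#' @param a,b \code{\linkS4class{BoundingBox}} objects.
#' @return A value in [0, 1].
#' @export
iouBox <- function(a, b) {
  ix <- min(a@xmin + a@w, b@xmin + b@w) - max(a@xmin, b@xmin)
  iy <- min(a@ymin + a@h, b@ymin + b@h) - max(a@ymin, b@ymin)
  inter <- max(0, ix) * max(0, iy)
  uni <- a@w * a@h + b@w * b@h - inter
  if (uni <= 0) return(0)
  inter / uni
}
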