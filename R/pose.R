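#' @include keypoint.R
NULL

#' Construct a ToolPose
#'
#' @param entry,hinge,tip1,tip2 \code{Keypoint} objects (or \code{NULL} for a
#'   missing slot).  Roles are enforced to match the slot.
#' @param transitions list of transition \code{Keypoint}s.
#' @param transitionEdges character vector naming, for each transition, the
#'   chain edge it lies on (\code{"entry-hinge"}, \code{"hinge-tip1"},
#'   \code{"hinge-tip2"}).
#' @param instanceId integer instance identifier.
#' @return A \code{\linkS4class{ToolPose}}.
#' @examples
#' p <- ToolPose(
#'   entry = Keypoint(480, 10, "entry"),
#'   hinge = Keypoint(450, 200, "hinge"),
#'   tip1  = Keypoint(430, 260, "tip1"),
#'   instanceId = 1L
#' )
#' validatePose(p, 960, 540)
#' @export
ToolPose <- function(entry = NULL, hinge = NULL, tip1 = NULL, tip2 = NULL,
                     transitions = list(), transitionEdges = character(),
                     instanceId = 1L) {
  fill <- function(kp, role) {
    if (is.null(kp)) return(missingKeypoint(role))
    if (kp@role != role)
      stop(sprintf("keypoint for slot '%s' has role '%s'", role, kp@role))
    kp
  }
  new("ToolPose",
      entry = fill(entry, "entry"), hinge = fill(hinge, "hinge"),
      tip1 = fill(tip1, "tip1"), tip2 = fill(tip2, "tip2"),
      transitions = transitions,
      transitionEdges = as.character(transitionEdges),
      instanceId = as.integer(instanceId))
}

#' @rdname accessors
#' @export
setMethod("entryPoint", "ToolPose", function(x) x@entry)
#' @rdname accessors
#' @export
setMethod("hingePoint", "ToolPose", function(x) x@hinge)
#' @rdname accessors
#' @export
setMethod("tipPoints", "ToolPose", function(x) list(x@tip1, x@tip2))
#' @rdname accessors
#' @export
setMethod("transitions", "ToolPose", function(x) x@transitions)
#' @rdname accessors
#' @export
setMethod("instanceId", "ToolPose", function(x) x@instanceId)

## Ordered list of the four canonical slots (internal).
poseSlots <- function(pose) {
  list(entry = pose@entry, hinge = pose@hinge,
       tip1 = pose@tip1, tip2 = pose@tip2)
}

#' @export
setMethod("show", "ToolPose", function(object) {
  sl <- poseSlots(object)
  tags <- vapply(sl, kpTag, character(1))
  cat(sprintf("ToolPose (instance %d): %s", object@instanceId,
              paste(sprintf("%s=%s", names(sl), tags), collapse = ", ")))
  if (length(object@transitions))
    cat(sprintf("; %d transition(s)", length(object@transitions)))
  cat("\n")
})

#' Check a pose against the labelling protocol
#'
#' Returns a character vector of human-readable violations, empty when the
#' pose conforms.  Checked rules:
#' \itemize{
#'   \item at least one of the four canonical slots is annotated
#'     (non-missing);
#'   \item every \emph{visible} keypoint (slots and transitions) lies inside
#'     the frame, i.e. \eqn{0 \le x < W} and \eqn{0 \le y < H} (half-open);
#'   \item occluded keypoints have finite coordinates (they may lie in the
#'     out-of-frame padding area);
#'   \item each transition is attached to a legal chain edge whose near
#'     endpoint is visible and whose far endpoint is occluded or missing (a
#'     transition marks the farthest visible position toward a non-visible
#'     endpoint).
#' }
#'
#' @param pose a \code{\linkS4class{ToolPose}}.
#' @param width,height frame dimensions in pixels.
#' @return character vector of violations (empty when valid).
#' @export
validatePose <- function(pose, width = 960, height = 540) {
  bad <- character()
  sl <- poseSlots(pose)
  tags <- vapply(sl, kpTag, character(1))
  if (all(tags == "missing"))
    bad <- c(bad, "empty pose: all four keypoint slots are missing")
  checkBounds <- function(kp, label) {
    if (kp@tag == "visible" &&
        (kp@x < 0 || kp@x >= width || kp@y < 0 || kp@y >= height))
      sprintf("visible out of bounds: %s at (%.6g, %.6g)", label, kp@x, kp@y)
    else if (kp@tag == "occluded" && (!is.finite(kp@x) || !is.finite(kp@y)))
      sprintf("occluded keypoint with non-finite coordinates: %s", label)
    else character()
  }
  for (nm in names(sl)) bad <- c(bad, checkBounds(sl[[nm]], nm))
  edgeEnds <- list(
    "entry-hinge" = c("entry", "hinge"),
    "hinge-tip1" = c("hinge", "tip1"),
    "hinge-tip2" = c("hinge", "tip2")
  )
  for (i in seq_along(pose@transitions)) {
    tr <- pose@transitions[[i]]
    lab <- sprintf("transition %d", i)
    bad <- c(bad, checkBounds(tr, lab))
    edge <- pose@transitionEdges[i]
    if (!edge %in% chainEdges()) {
      bad <- c(bad, sprintf("illegal edge for %s: '%s'", lab, edge))
      next
    }
    et <- tags[edgeEnds[[edge]]]
    if (sum(et == "visible") != 1L)
      bad <- c(bad, sprintf(
        "transition placement: %s on edge %s whose endpoints are %s/%s",
        lab, edge, et[1], et[2]))
  }
  bad
}

#' Construct a FrameAnnotation
#'
#' @param poses list of \code{ToolPose}.
#' @param frameId frame identifier string.
#' @param width,height frame dimensions in pixels (default 960 x 540, the
#'   downsampled endoscopic frame size).
#' @param maskPath optional path of the paired instance mask.
#' @param extra named list of opaque extra fields carried through
#'   serialization.
#' @return A \code{\linkS4class{FrameAnnotation}}.
#' @export
FrameAnnotation <- function(poses = list(), frameId = "frame",
                            width = 960, height = 540,
                            maskPath = NA_character_, extra = list()) {
  new("FrameAnnotation", frameId = as.character(frameId),
      width = as.numeric(width), height = as.numeric(height),
      poses = poses, maskPath = as.character(maskPath), extra = extra)
}

#' @rdname accessors
#' @export
setMethod("frameId", "FrameAnnotation", function(x) x@frameId)
#' @rdname accessors
#' @export
setMethod("frameSize", "FrameAnnotation",
          function(x) c(width = x@width, height = x@height))
#' @rdname accessors
#' @export
setMethod("poses", "FrameAnnotation", function(x) x@poses)

#' @export
setMethod("show", "FrameAnnotation", function(object) {
  cat(sprintf("FrameAnnotation '%s' (%g x %g) with %d pose(s)\n",
              object@frameId, object@width, object@height,
              length(object@poses)))
})

#' Validate every pose of a frame
#'
#' @param frame a \code{\linkS4class{FrameAnnotation}}.
#' @return data.frame with columns \code{instanceId} and \code{violation};
#'   zero rows when the frame is clean.
#' @export
validateFrame <- function(frame) {
  out <- lapply(frame@poses, function(p) {
    v <- validatePose(p, frame@width, frame@height)
    if (length(v))
      data.frame(instanceId = p@instanceId, violation = v)
    else
      NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    data.frame(instanceId = integer(), violation = character())
  else out
}
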