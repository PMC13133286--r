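#' @include AllGenerics.R
NULL

#' Construct a Keypoint
#'
#' Missing keypoints are normalised to the (0, 0) coordinate sentinel; their
#' coordinates are never used in arithmetic (exclusion is by tag).
#'
#' @param x,y pixel coordinates (0-based, origin at the top-left corner of the
#'   top-left pixel).
#' @param role one of \code{\link{keypointRoles}()}.
#' @param tag one of \code{\link{visibilityStates}()}.
#' @return A \code{\linkS4class{Keypoint}}.
#' @examples
#' Keypoint(480, 270, "hinge", "visible")
#' missingKeypoint("tip2")
#' @export
Keypoint <- function(x, y, role, tag = "visible") {
  role <- match.arg(role, keypointRoles())
  tag <- match.arg(tag, visibilityStates())
  if (tag == "missing") { x <- 0; y <- 0 }
  new("Keypoint", x = as.numeric(x), y = as.numeric(y), role = role, tag = tag)
}

#' @rdname Keypoint
#' @export
missingKeypoint <- function(role) Keypoint(0, 0, role, "missing")

#' @rdname accessors
#' @export
kpX <- function(x) x@x
#' @rdname accessors
#' @export
kpY <- function(x) x@y
#' @rdname accessors
#' @export
kpRole <- function(x) x@role
#' @rdname accessors
#' @export
kpTag <- function(x) x@tag

#' @export
setMethod("show", "Keypoint", function(object) {
  cat(sprintf("Keypoint %s (%s) at (%.2f, %.2f)\n",
              object@role, object@tag, object@x, object@y))
})
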