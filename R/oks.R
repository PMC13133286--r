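#' @include coco.R
NULL

#' Construct the keypoint-metric parameter set
#'
#' The per-keypoint scale-normalised standard deviation defaults to the
#' conservative value 0.107 for all four roles (the largest value used for
#' human keypoints, reflecting the geometric ambiguity of smooth metallic
#' tools), with falloff \eqn{\kappa_i = 2 \sigma_i}.  AP/AR are summarised
#' over similarity thresholds 0.50 to 0.95 in steps of 0.05, with at most
#' \code{maxDetections} detections per image, and the tip-permutation
#' invariant similarity enabled by default.
#'
#' @param sigma scalar or length-4 numeric.
#' @param oksThresholds strictly increasing thresholds in (0, 1).
#' @param maxDetections per-image detection cap.
#' @param tipSwap logical, evaluate both tip orderings and keep the best.
#' @return An \code{\linkS4class{OksParams}}.
#' @export
OksParams <- function(sigma = 0.107, oksThresholds = seq(0.5, 0.95, by = 0.05),
                      maxDetections = 20L, tipSwap = TRUE) {
  sigma <- rep_len(as.numeric(sigma), 4L)
  new("OksParams", sigma = sigma, kappa = 2 * sigma,
      oksThresholds = as.numeric(oksThresholds),
      maxDetections = as.integer(maxDetections), tipSwap = tipSwap)
}

#' Rotation-robust object scale of a bounding box
#'
#' The scale entering the keypoint similarity is
#' \deqn{s = \sqrt{(w^2 + h^2)/2},}
#' the root-mean-square of the box dimensions (a scaled diagonal), instead of
#' the conventional \eqn{\sqrt{wh}}.  For slender, elongated tools the
#' axis-aligned box area collapses when the tool is horizontal or vertical;
#' the RMS form is invariant under swapping \eqn{w} and \eqn{h}, dominated by
#' the tool length, and satisfies \eqn{s^2 \ge wh} (AM--GM) with equality iff
#' \eqn{w = h}, where it reduces to the conventional definition.
#'
#' @param box a \code{\linkS4class{BoundingBox}}, or a numeric width if
#'   \code{h} is given.
#' @param h box height when \code{box} is a width.
#' @return Scale \eqn{s} in pixels.
#' @examples
#' scaleFactor(100, 100)  # 100
#' scaleFactor(300, 40)   # sqrt(45800)
#' @export
scaleFactor <- function(box, h = NULL) {
  if (is(box, "BoundingBox")) { w <- box@w; hh <- box@h }
  else { w <- as.numeric(box); hh <- as.numeric(h) }
  if (w == 0 && hh == 0)
    schemaError("degenerate box: w = h = 0 has no scale")
  sqrt((w^2 + hh^2) / 2)
}

asTriplets <- function(x) {
  if (is(x, "CocoAnnotation") || is(x, "ScoredDetection"))
    return(keypointTriplets(x))
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3, nrow(x) == 4)
    return(x)
  }
  stopifnot(length(x) == 12)
  matrix(as.numeric(x), ncol = 3, byrow = TRUE)
}

#' Object Keypoint Similarity between one prediction and one ground truth
#'
#' \deqn{OKS = \frac{\sum_i \exp(-d_i^2 / (2 s^2 \kappa_i^2))\,
#'   \delta(v_i > 0)}{\sum_i \delta(v_i > 0)}}
#' where \eqn{d_i} is the Euclidean distance between predicted and
#' ground-truth keypoint \eqn{i}, \eqn{s} the object scale and \eqn{\kappa_i}
#' the per-keypoint falloff.  Only ground-truth visibility counts: keypoints
#' with \eqn{v_i = 0} contribute nothing, and predicted visibility codes are
#' ignored entirely.
#'
#' @param pred,gt 4 (x, y, v) triplets each: a length-12 vector, a 4x3
#'   matrix, a \code{\linkS4class{ScoredDetection}} or a
#'   \code{\linkS4class{CocoAnnotation}}.
#' @param s object scale in pixels (see \code{\link{scaleFactor}}).
#' @param params an \code{\linkS4class{OksParams}}.
#' @return Similarity in [0, 1]; \code{NA} if the ground truth has no
#'   labelled keypoint (such instances are ignore-instances for the matcher).
#' @examples
#' gt <- c(100, 100, 2, 200, 150, 2, 260, 180, 2, 255, 120, 2)
#' oks(gt, gt, s = 150, OksParams())  # 1
#' @export
oks <- function(pred, gt, s, params = OksParams()) {
  if (s <= 0) schemaError("object scale must be positive")
  p <- asTriplets(pred); g <- asTriplets(gt)
  use <- g[, 3] > 0
  if (!any(use)) return(NA_real_)
  d2 <- (p[use, 1] - g[use, 1])^2 + (p[use, 2] - g[use, 2])^2
  mean(exp(-d2 / (2 * s^2 * params@kappa[use]^2)))
}

## Exchange the Tip1/Tip2 triplets (coordinates and v codes move together).
swapTips <- function(trip) {
  trip <- asTriplets(trip)
  trip[c(1, 2, 4, 3), , drop = FALSE]
}

#' Tip-permutation-invariant keypoint similarity
#'
#' Tip1 and Tip2 of symmetric jaws are an unordered set, but the plain
#' similarity compares them slot-by-slot.  This variant evaluates the
#' prediction against the original ground truth and against a copy with the
#' two tip triplets exchanged, and reports the better value — equivalent to a
#' bipartite matching step over the two tips.
#'
#' @inheritParams oks
#' @return Similarity in [0, 1]; always \eqn{\ge} the plain \code{\link{oks}}.
#' @export
oksTipSwap <- function(pred, gt, s, params = OksParams()) {
  g <- asTriplets(gt)
  a <- oks(pred, g, s, params)
  b <- oks(pred, swapTips(g), s, params)
  if (is.na(a)) return(a)
  max(a, b)
}
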