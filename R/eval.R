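#' @include oks.R
NULL

## Greedy matcher of the COCO protocol.  `sim` is a detections x ground-truth
## similarity matrix with detections already in descending score order and
## ground truths ordered ignore-last.  For every threshold, each detection is
## assigned to the not-yet-matched ground truth of maximal similarity >= the
## threshold, preferring non-ignore instances; a candidate of equal
## similarity encountered later replaces the current one (reference
## behaviour).  Matches to ignore instances mark the detection as ignored
## (it neither rewards nor penalises precision).
cocoMatchCore <- function(sim, gtIgnore, thresholds) {
  nd <- nrow(sim); ng <- ncol(sim)
  nt <- length(thresholds)
  dtm <- matrix(0L, nt, nd)
  gtm <- matrix(0L, nt, ng)
  dtIg <- matrix(FALSE, nt, nd)
  for (ti in seq_len(nt)) {
    for (d in seq_len(nd)) {
      best <- min(thresholds[ti], 1 - 1e-10)
      m <- 0L
      for (g in seq_len(ng)) {
        if (gtm[ti, g] > 0L) next
        if (m > 0L && !gtIgnore[m] && gtIgnore[g]) break
        if (sim[d, g] < best) next
        best <- sim[d, g]
        m <- g
      }
      if (m == 0L) next
      dtIg[ti, d] <- gtIgnore[m]
      dtm[ti, d] <- m
      gtm[ti, m] <- d
    }
  }
  list(dtm = dtm, gtm = gtm, dtIg = dtIg)
}

#' Greedy COCO-protocol matching of detections to ground truths
#'
#' Detections are processed in descending score order (capped at
#' \code{maxDetections}); each is matched to the unmatched ground truth of
#' maximal similarity, provided that similarity reaches \code{threshold}.
#' Ground truths with no labelled keypoint are ignore-instances: a detection
#' whose best admissible match is an ignore instance is excluded from the
#' precision denominator rather than counted as a false positive.
#'
#' @param dets list of \code{\linkS4class{ScoredDetection}}.
#' @param gts list of \code{\linkS4class{CocoAnnotation}}.
#' @param similarity matrix \code{length(dets)} x \code{length(gts)} of
#'   precomputed similarities (tip-swap OKS or IoU), in input order.
#' @param threshold minimal similarity for a match.
#' @param maxDetections detection cap.
#' @return list with \code{detMatch} (ground-truth index per detection, 0 =
#'   unmatched, NA = dropped by the cap), \code{gtMatch} (detection index per
#'   ground truth, 0 = unmatched) and \code{detIgnore} (logical).
#' @export
greedyMatch <- function(dets, gts, similarity, threshold,
                        maxDetections = 20L) {
  scores <- vapply(dets, function(d) d@score, numeric(1))
  dord <- order(-scores, seq_along(scores))
  dord <- dord[seq_len(min(length(dord), maxDetections))]
  ig <- vapply(gts, function(g) g@numKeypoints == 0L, logical(1))
  gord <- order(ig, seq_along(ig))
  m <- cocoMatchCore(similarity[dord, gord, drop = FALSE], ig[gord],
                     threshold)
  detMatch <- rep(NA_integer_, length(dets))
  detIgnore <- rep(NA, length(dets))
  detMatch[dord] <- ifelse(m$dtm[1, ] > 0L, gord[pmax(m$dtm[1, ], 1L)], 0L)
  detIgnore[dord] <- m$dtIg[1, ]
  gtMatch <- integer(length(gts))
  gtMatch[gord] <- ifelse(m$gtm[1, ] > 0L, dord[pmax(m$gtm[1, ], 1L)], 0L)
  list(detMatch = detMatch, gtMatch = gtMatch, detIgnore = detIgnore)
}

## Pseudo-similarity of a detection to an ignore ground truth without
## labelled keypoints: Gaussian falloff of the keypoints' distance to the
## doubly-expanded ground-truth box (reference-protocol behaviour), so that
## detections sitting on unlabellable instances can be discarded rather than
## penalised.
oksToBox <- function(det, bb, s, params) {
  tp <- asTriplets(det)
  x0 <- bb@xmin - bb@w; x1 <- bb@xmin + 2 * bb@w
  y0 <- bb@ymin - bb@h; y1 <- bb@ymin + 2 * bb@h
  dx <- pmax(0, x0 - tp[, 1]) + pmax(0, tp[, 1] - x1)
  dy <- pmax(0, y0 - tp[, 2]) + pmax(0, tp[, 2] - y1)
  mean(exp(-(dx^2 + dy^2) / (2 * s^2 * params@kappa^2)))
}

detectionBox <- function(det, width, height, margin = 20) {
  if (!is.null(det@bbox)) return(det@bbox)
  tp <- asTriplets(det)
  use <- tp[, 3] > 0
  if (!any(use)) use <- rep(TRUE, 4)
  x0 <- max(0, min(tp[use, 1]) - margin)
  y0 <- max(0, min(tp[use, 2]) - margin)
  x1 <- min(width, max(tp[use, 1]) + margin)
  y1 <- min(height, max(tp[use, 2]) + margin)
  BoundingBox(x0, y0, x1 - x0, y1 - y0)
}

## Shared evaluation loop; simFun(dets, gts, width, height) returns the
## similarity matrix for one image.
evalCore <- function(gt, dets, thresholds, maxDetections, simFun, protocol) {
  imgs <- gt@images
  detImg <- vapply(dets, function(d) d@imageId, integer(1))
  if (length(detImg) && !all(detImg %in% imgs$id))
    schemaError("detection image_id does not resolve: %s",
                paste(unique(detImg[!detImg %in% imgs$id]), collapse = ", "))
  annImg <- vapply(gt@annotations, function(a) a@imageId, integer(1))

  perImage <- lapply(seq_len(nrow(imgs)), function(i) {
    id <- imgs$id[i]
    ganns <- gt@annotations[annImg == id]
    ig <- vapply(ganns, function(g) g@numKeypoints == 0L, logical(1))
    gord <- order(ig, seq_along(ig))
    ganns <- ganns[gord]; ig <- ig[gord]
    danns <- dets[detImg == id]
    scores <- vapply(danns, function(d) d@score, numeric(1))
    dord <- order(-scores, seq_along(scores))
    dord <- dord[seq_len(min(length(dord), maxDetections))]
    danns <- danns[dord]; scores <- scores[dord]
    sim <- simFun(danns, ganns, imgs$width[i], imgs$height[i])
    m <- cocoMatchCore(sim, ig, thresholds)
    list(scores = scores, dtm = m$dtm, dtIg = m$dtIg,
         nNonIgnore = sum(!ig))
  })

  recallGrid <- seq(0, 1, by = 0.01)
  nt <- length(thresholds); nr <- length(recallGrid)
  npig <- sum(vapply(perImage, function(x) x$nNonIgnore, numeric(1)))
  precision <- matrix(-1, nt, nr)
  recall <- rep(-1, nt)
  if (npig > 0) {
    scores <- unlist(lapply(perImage, function(x) x$scores))
    ord <- order(-scores, seq_along(scores))
    for (ti in seq_len(nt)) {
      matched <- unlist(lapply(perImage, function(x) x$dtm[ti, ]))[ord]
      ignored <- unlist(lapply(perImage, function(x) x$dtIg[ti, ]))[ord]
      matched <- matched[!ignored]
      nd <- length(matched)
      if (nd == 0L) { recall[ti] <- 0; precision[ti, ] <- 0; next }
      tp <- cumsum(matched > 0L)
      fp <- cumsum(matched == 0L)
      rc <- tp / npig
      pr <- tp / (tp + fp + .Machine$double.eps)
      recall[ti] <- rc[nd]
      # interpolated precision: monotone non-increasing from the right
      if (nd > 1L) for (i in (nd - 1L):1L) pr[i] <- max(pr[i], pr[i + 1L])
      ind <- vapply(recallGrid, function(r) sum(rc < r), integer(1)) + 1L
      precision[ti, ] <- ifelse(ind <= nd, pr[pmin(ind, nd)], 0)
    }
  }
  at <- function(v, th) {
    i <- which(abs(thresholds - th) < 1e-9)
    if (length(i) != 1L) return(NA_real_)
    v[i]
  }
  prAt <- function(th) {
    i <- which(abs(thresholds - th) < 1e-9)
    if (length(i) != 1L) return(NA_real_)
    if (npig == 0) -1 else mean(precision[i, ])
  }
  new("EvalSummary", protocol = protocol, thresholds = thresholds,
      apMean = if (npig == 0) -1 else mean(precision),
      ap050 = prAt(0.5), ap075 = prAt(0.75),
      arMean = if (npig == 0) -1 else mean(recall),
      ar050 = at(recall, 0.5), ar075 = at(recall, 0.75),
      precision = precision, recall = recall, recallGrid = recallGrid)
}

#' Evaluate pose detections with the keypoint-similarity protocol
#'
#' COCO-protocol average precision and recall over the OKS threshold grid.
#' The object scale of each ground truth is derived from its stored bounding
#' box as \eqn{s = \sqrt{(w^2+h^2)/2}} (see \code{\link{scaleFactor}});
#' the tip-permutation-invariant similarity is used unless
#' \code{params@tipSwap} is off.  Ground truths without labelled keypoints
#' are ignore-instances.  An evaluation with no evaluable ground truth
#' reports the -1 sentinel in every field.
#'
#' @param gt a \code{\linkS4class{CocoDataset}}.
#' @param dets list of \code{\linkS4class{ScoredDetection}} whose image ids
#'   all resolve in \code{gt}.
#' @param params an \code{\linkS4class{OksParams}}.
#' @return An \code{\linkS4class{EvalSummary}}.
#' @export
evaluatePose <- function(gt, dets, params = OksParams()) {
  simFun <- function(danns, ganns, width, height) {
    sim <- matrix(0, length(danns), length(ganns))
    for (j in seq_along(ganns)) {
      g <- ganns[[j]]
      s <- sqrt((g@bbox@w^2 + g@bbox@h^2) / 2 + .Machine$double.eps)
      for (i in seq_along(danns)) {
        sim[i, j] <- if (g@numKeypoints > 0L) {
          if (params@tipSwap) oksTipSwap(danns[[i]], g, s, params)
          else oks(danns[[i]], g, s, params)
        } else oksToBox(danns[[i]], g@bbox, s, params)
      }
    }
    sim
  }
  evalCore(gt, dets, params@oksThresholds, params@maxDetections, simFun,
           protocol = "OKS")
}

#' Evaluate detection boxes with the IoU protocol
#'
#' COCO-style box AP/AR over IoU thresholds 0.50--0.95.  Detections without
#' a stored box get one derived from their keypoints (20 px margin, clipped).
#'
#' @inheritParams evaluatePose
#' @param iouThresholds strictly increasing IoU thresholds.
#' @param maxDetections per-image detection cap.
#' @return An \code{\linkS4class{EvalSummary}}.
#' @export
evaluateBbox <- function(gt, dets, iouThresholds = seq(0.5, 0.95, by = 0.05),
                         maxDetections = 20L) {
  simFun <- function(danns, ganns, width, height) {
    sim <- matrix(0, length(danns), length(ganns))
    for (j in seq_along(ganns))
      for (i in seq_along(danns))
        sim[i, j] <- iouBox(detectionBox(danns[[i]], width, height),
                            ganns[[j]]@bbox)
    sim
  }
  evalCore(gt, dets, iouThresholds, maxDetections, simFun, protocol = "IoU")
}

#' Headline AP/AR table of an evaluation
#'
#' One row in the conventional benchmark column layout:
#' AP, AP@0.5, AP@0.75, AR, AR@0.5, AR@0.75.
#'
#' @param x an \code{\linkS4class{EvalSummary}}.
#' @param ... unused.
#' @return A one-row data.frame.
#' @export
setMethod("summaryTable", "EvalSummary", function(x, ...) {
  data.frame(protocol = x@protocol,
             AP = x@apMean, AP50 = x@ap050, AP75 = x@ap075,
             AR = x@arMean, AR50 = x@ar050, AR75 = x@ar075)
})

#' @export
setMethod("show", "EvalSummary", function(object) {
  cat(sprintf("EvalSummary (%s protocol, %d thresholds)\n",
              object@protocol, length(object@thresholds)))
  cat(sprintf("  AP      AP@0.5  AP@0.75 AR      AR@0.5  AR@0.75\n"))
  cat(sprintf("  %-7.3f %-7.3f %-7.3f %-7.3f %-7.3f %-7.3f\n",
              object@apMean, object@ap050, object@ap075,
              object@arMean, object@ar050, object@ar075))
})

#' Write an evaluation summary as machine-readable JSON
#'
#' @param x an \code{\linkS4class{EvalSummary}} or a named list of them.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeEvalSummary <- function(x, path) {
  one <- function(s) list(
    protocol = s@protocol,
    thresholds = s@thresholds,
    ap = s@apMean, ap_050 = s@ap050, ap_075 = s@ap075,
    ar = s@arMean, ar_050 = s@ar050, ar_075 = s@ar075,
    recall_per_threshold = s@recall,
    precision_curves = apply(s@precision, 1, identity, simplify = FALSE)
  )
  doc <- list(schema_version = 1L)
  if (is(x, "EvalSummary")) doc$summary <- one(x)
  else doc <- c(doc, lapply(x, one))
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           digits = NA)), path)
  invisible(path)
}
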