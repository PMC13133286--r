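# Independent reference implementation of the COCO evaluation protocol,
# used to cross-check the package evaluator.  It works on plain lists and
# follows the published matching/accumulation algorithm with a deliberately
# different code path: candidate-set matching (prefer non-ignore; on ties
# the later ground truth wins), unfiltered cumulative sums, and interpolated
# precision computed directly as max precision at recall >= r.
# No tip-swap: comparisons against it are run with tip-swap disabled.

oracleSimilarity <- function(d, g, kind, kappa2) {
  if (kind == "iou") {
    a <- g$bbox; b <- d$bbox
    iw <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
    ih <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    inter <- iw * ih
    u <- a[3] * a[4] + b[3] * b[4] - inter
    return(if (u <= 0) 0 else inter / u)
  }
  s2 <- (g$bbox[3]^2 + g$bbox[4]^2) / 2 + .Machine$double.eps
  p <- matrix(d$kp, ncol = 3, byrow = TRUE)
  gm <- matrix(g$kp, ncol = 3, byrow = TRUE)
  lab <- gm[, 3] > 0
  if (any(lab)) {
    dd <- (p[lab, 1] - gm[lab, 1])^2 + (p[lab, 2] - gm[lab, 2])^2
    sum(exp(-dd / (2 * s2 * kappa2[lab]))) / sum(lab)
  } else {
    bb <- g$bbox
    xlo <- bb[1] - bb[3]; xhi <- bb[1] + 2 * bb[3]
    ylo <- bb[2] - bb[4]; yhi <- bb[2] + 2 * bb[4]
    ddx <- pmax(0, xlo - p[, 1]) + pmax(0, p[, 1] - xhi)
    ddy <- pmax(0, ylo - p[, 2]) + pmax(0, p[, 2] - yhi)
    sum(exp(-(ddx^2 + ddy^2) / (2 * s2 * kappa2))) / 4
  }
}

# gtsByImage/detsByImage: lists (one element per image, in images-table
# order) of lists with fields kp, bbox, nkp / kp, bbox, score.
oracleEvaluate <- function(gtsByImage, detsByImage, thresholds,
                           kind = c("oks", "iou"),
                           sigma = rep(0.107, 4), maxDet = 20L) {
  kind <- match.arg(kind)
  kappa2 <- (2 * sigma)^2
  nT <- length(thresholds)
  grid <- seq(0, 1, by = 0.01)

  allScores <- numeric(0)
  allMatched <- vector("list", nT)
  allIgnored <- vector("list", nT)
  for (ti in seq_len(nT)) { allMatched[[ti]] <- logical(0); allIgnored[[ti]] <- logical(0) }
  npig <- 0L

  for (ii in seq_along(gtsByImage)) {
    gimg <- gtsByImage[[ii]]
    dimg <- detsByImage[[ii]]
    scores <- vapply(dimg, `[[`, numeric(1), "score")
    ord <- order(-scores, seq_along(scores))
    ord <- ord[seq_len(min(length(ord), maxDet))]
    dimg <- dimg[ord]; scores <- scores[ord]
    ig <- vapply(gimg, function(g) g$nkp == 0, logical(1))
    npig <- npig + sum(!ig)
    nd <- length(dimg); ng <- length(gimg)
    sim <- matrix(0, nd, ng)
    for (i in seq_len(nd))
      for (j in seq_len(ng))
        sim[i, j] <- oracleSimilarity(dimg[[i]], gimg[[j]], kind, kappa2)
    for (ti in seq_len(nT)) {
      thr <- min(thresholds[ti], 1 - 1e-10)
      taken <- rep(FALSE, ng)
      matched <- rep(FALSE, nd)
      ignored <- rep(FALSE, nd)
      for (i in seq_len(nd)) {
        cand <- which(!taken & sim[i, ] >= thr)
        pick <- NA_integer_
        reg <- cand[!ig[cand]]
        if (length(reg)) {
          best <- max(sim[i, reg])
          pick <- max(reg[sim[i, reg] == best])  # later gt wins ties
        } else if (length(cand)) {
          best <- max(sim[i, cand])
          pick <- max(cand[sim[i, cand] == best])
        }
        if (!is.na(pick)) {
          taken[pick] <- TRUE
          matched[i] <- TRUE
          ignored[i] <- ig[pick]
        }
      }
      allMatched[[ti]] <- c(allMatched[[ti]], matched)
      allIgnored[[ti]] <- c(allIgnored[[ti]], ignored)
    }
    allScores <- c(allScores, scores)
  }

  precision <- matrix(-1, nT, length(grid))
  recall <- rep(-1, nT)
  if (npig > 0) {
    gord <- order(-allScores, seq_along(allScores))
    for (ti in seq_len(nT)) {
      m <- allMatched[[ti]][gord]
      ign <- allIgnored[[ti]][gord]
      tps <- cumsum(m & !ign)
      fps <- cumsum(!m & !ign)
      rc <- tps / npig
      pr <- tps / (tps + fps + .Machine$double.eps)
      recall[ti] <- if (length(rc)) rc[length(rc)] else 0
      precision[ti, ] <- vapply(grid, function(r) {
        sel <- rc >= r
        if (any(sel)) max(pr[sel]) else 0
      }, numeric(1))
    }
  }
  iAt <- function(th) which(abs(thresholds - th) < 1e-9)
  list(
    ap = if (npig == 0) -1 else mean(precision),
    ap050 = if (npig == 0) -1 else mean(precision[iAt(0.5), ]),
    ap075 = if (npig == 0) -1 else mean(precision[iAt(0.75), ]),
    ar = if (npig == 0) -1 else mean(recall),
    ar050 = recall[iAt(0.5)],
    ar075 = recall[iAt(0.75)],
    precision = precision, recall = recall
  )
}

# Adapters from the package's containers to the oracle's plain lists.
oracleGtInputs <- function(ds) {
  anns <- annotations(ds)
  annImg <- vapply(anns, function(a) a@imageId, integer(1))
  lapply(images(ds)$id, function(id)
    lapply(anns[annImg == id], function(a)
      list(kp = a@keypoints, bbox = unname(bboxVector(a@bbox)),
           nkp = a@numKeypoints)))
}

oracleDetInputs <- function(ds, dets) {
  detImg <- vapply(dets, function(d) d@imageId, integer(1))
  lapply(images(ds)$id, function(id)
    lapply(dets[detImg == id], function(d)
      list(kp = d@keypoints,
           bbox = if (is.null(d@bbox)) c(0, 0, 0, 0)
                  else unname(bboxVector(d@bbox)),
           score = d@score)))
}
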