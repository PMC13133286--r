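#' @include eval.R
NULL

#' Construct an InstanceMask
#'
#' @param labels integer matrix of instance labels, indexed
#'   \code{[y + 1, x + 1]}; 0 is background.
#' @return An \code{\linkS4class{InstanceMask}}.
#' @export
InstanceMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("InstanceMask", labels = labels)
}

#' @rdname accessors
#' @export
setMethod("maskLabels", "InstanceMask", function(x) x@labels)

#' @export
setMethod("show", "InstanceMask", function(object) {
  ids <- sort(setdiff(unique(as.vector(object@labels)), 0L))
  cat(sprintf("InstanceMask %d x %d, %d instance(s)%s\n",
              ncol(object@labels), nrow(object@labels), length(ids),
              if (length(ids)) paste0(" (ids ",
                                      paste(ids, collapse = ", "), ")")
              else ""))
})

## ---- minimal 16-bit grayscale PNG encoder ----------------------------------
## png::writePNG only emits 8-bit files; label images with ids above 255 are
## written with this encoder (single-channel, bit depth 16, no interlacing)
## and read back through libpng.

.crcTable <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  for (n in 0:255) {
    cc <- n
    for (k in 1:8)
      cc <- if (bitwAnd(cc, 1L)) bitwXor(poly, bitwShiftR(cc, 1L))
            else bitwShiftR(cc, 1L)
    tab[n + 1L] <- cc
  }
  tab
})

crc32 <- function(bytes) {
  cc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b))
    cc <- bitwXor(bitwShiftR(cc, 8L),
                  .crcTable[bitwAnd(bitwXor(cc, b[i]), 255L) + 1L])
  cc <- bitwXor(cc, -1L)
  if (cc < 0) cc + 2^32 else as.numeric(cc)
}

adler32 <- function(bytes) {
  s <- as.numeric(bytes)
  n <- length(s)
  a <- (1 + sum(s)) %% 65521
  b <- (n + sum(cumsum(s))) %% 65521
  b * 65536 + a
}

packUint32 <- function(u)
  as.raw(c(u %/% 16777216 %% 256, u %/% 65536 %% 256, u %/% 256 %% 256,
           u %% 256))

pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(packUint32(length(data)), body, packUint32(crc32(body)))
}

## zlib stream for the IDAT chunk.  memCompress(type = "gzip") emits a zlib
## container (0x78 header, Adler-32 trailer) which is what PNG wants; if a
## build ever returns a true gzip container (0x1f 0x8b), strip its 10-byte
## header and 8-byte trailer and re-wrap the deflate payload as zlib.
zlibWrap <- function(bytes) {
  z <- memCompress(bytes, type = "gzip")
  if (length(z) >= 2 && z[1] == as.raw(0x1f) && z[2] == as.raw(0x8b)) {
    stopifnot(length(z) > 18, z[4] == as.raw(0))  # FLG must be 0
    z <- c(as.raw(c(0x78, 0x9c)), z[11:(length(z) - 8L)],
           packUint32(adler32(bytes)))
  }
  z
}

writePng16 <- function(labels, path) {
  h <- nrow(labels); w <- ncol(labels)
  ihdr <- c(packUint32(w), packUint32(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, grayscale
  hi <- labels %/% 256L; lo <- labels %% 256L
  scan <- unlist(lapply(seq_len(h), function(r)
    c(0L, as.vector(rbind(hi[r, ], lo[r, ])))))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(pngChunk("IHDR", ihdr), con)
  writeBin(pngChunk("IDAT", zlibWrap(as.raw(scan))), con)
  writeBin(pngChunk("IEND", raw(0)), con)
  invisible(path)
}

#' Read / write instance masks as single-channel label PNG
#'
#' The mask dialect is a single-channel PNG whose pixel value is the
#' instance id (0 = background): 8-bit for up to 255 instances, 16-bit
#' beyond.  The round trip \code{readMask(writeMask(m))} is lossless at
#' pixel level.
#'
#' @param path PNG file path (conventionally
#'   \code{instrument_instances.png}).
#' @param mask an \code{\linkS4class{InstanceMask}} (for writing).
#' @return \code{readMask}: an \code{InstanceMask}; \code{writeMask}: the
#'   path, invisibly.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) parseError("no such file: %s", path)
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      schemaError("mask must be single-channel, got %d channels",
                  dim(img)[3])
    img <- img[, , 1]
  }
  depth <- if (is.null(info$bit.depth)) 8L else info$bit.depth
  InstanceMask(matrix(as.integer(round(img * (2^depth - 1))),
                      nrow = nrow(img)))
}

#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  lab <- mask@labels
  if (max(lab, 0L) <= 255L)
    png::writePNG(lab / 255, path)
  else
    writePng16(lab, path)
  invisible(path)
}

#' Remove instances from a mask
#'
#' Pixels whose label is in \code{ids} are set to background; all other
#' pixels are untouched and surviving ids keep their values (no
#' re-indexing), preserving cross-file instance identity.  Removing every
#' present id yields a completely empty (black) label image, as when
#' access-port (trocar cannula) instances are stripped from a frame that
#' contains nothing else.
#'
#' @param mask an \code{\linkS4class{InstanceMask}}.
#' @param ids integer ids to remove; absent ids are no-ops.
#' @return A new \code{InstanceMask}; the input is unmodified.
#' @export
removeInstances <- function(mask, ids) {
  lab <- mask@labels
  lab[lab %in% as.integer(ids)] <- 0L
  InstanceMask(lab)
}

#' Fraction of visible keypoints supported by the mask
#'
#' Quality-control heuristic: the fraction of a pose's visible canonical
#' keypoints that have at least one non-background mask pixel within
#' \code{radius} pixels (Euclidean distance to pixel centres).
#'
#' @param pose a \code{\linkS4class{ToolPose}}.
#' @param mask an \code{\linkS4class{InstanceMask}} of the paired frame.
#' @param radius search radius in pixels (>= 0).
#' @return Fraction in [0, 1], or \code{NA} when the pose has no visible
#'   keypoint.
#' @export
poseMaskConsistency <- function(pose, mask, radius) {
  stopifnot(radius >= 0)
  lab <- mask@labels
  h <- nrow(lab); w <- ncol(lab)
  sl <- poseSlots(pose)
  vis <- Filter(function(k) k@tag == "visible", sl)
  if (!length(vis)) return(NA_real_)
  hit <- vapply(vis, function(k) {
    # pixel (row r, col c) has centre (c - 0.5, r - 0.5) in image coordinates
    r0 <- max(1L, floor(k@y - radius + 0.5)); r1 <- min(h, ceiling(k@y + radius + 0.5))
    c0 <- max(1L, floor(k@x - radius + 0.5)); c1 <- min(w, ceiling(k@x + radius + 0.5))
    if (r0 > r1 || c0 > c1) return(FALSE)
    sub <- lab[r0:r1, c0:c1, drop = FALSE]
    if (all(sub == 0L)) return(FALSE)
    dy <- (r0:r1) - 0.5 - k@y
    dx <- (c0:c1) - 0.5 - k@x
    d2 <- outer(dy^2, dx^2, `+`)
    any(sub > 0L & d2 <= radius^2)
  }, logical(1))
  mean(hit)
}
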