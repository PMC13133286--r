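#' @include pose.R
NULL

## Classed conditions so the CLI can map failures onto exit codes.
schemaError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tpk_schema_error", "error", "condition")))
}
parseError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("tpk_parse_error", "error", "condition")))
}

roleAbbrev <- c(entry = "E", hinge = "H", tip1 = "T1", tip2 = "T2",
                transition = "TR")

#' Parse the per-frame annotation JSON dialect
#'
#' The dialect carries four parallel structures: \code{nodes} (list of
#' \code{[x, y]} pairs), \code{tags} (strings \code{"ROLE:visibility"} with
#' roles E, H, T1, T2 and TR for transition points), \code{edges} (0-based
#' \code{[i, j]} index pairs) and \code{transitions} (0-based indices of the
#' transition nodes).  A transition point splits the chain edge it sits on
#' into two index pairs.  Distinct instruments are distinct connected
#' components of the edge graph; after contracting transition nodes the
#' recovered edges must belong to the legal chain
#' Entry--Hinge, Hinge--Tip1, Hinge--Tip2.
#' Unknown top-level fields are preserved opaquely in the \code{extra} slot.
#'
#' @param text a JSON document as a single string.
#' @param width,height frame dimensions in pixels.
#' @param frameId identifier stored on the result.
#' @return A \code{\linkS4class{FrameAnnotation}}.
#' @seealso \code{\link{serializeRawJson}}, \code{\link{readRawJson}}
#' @export
parseRawJson <- function(text, width = 960, height = 540, frameId = "frame") {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) parseError("malformed JSON: %s",
                                                 conditionMessage(e)))
  if (!is.list(doc)) parseError("top-level JSON value must be an object")
  for (f in c("nodes", "tags", "edges", "transitions"))
    if (is.null(doc[[f]])) schemaError("missing required field '%s'", f)

  nodes <- doc$nodes
  tags <- doc$tags
  n <- length(nodes)
  if (length(tags) != n)
    schemaError("tags (%d) not parallel to nodes (%d)", length(tags), n)
  xy <- matrix(NA_real_, nrow = max(n, 0L), ncol = 2)
  for (i in seq_len(n)) {
    nd <- unlist(nodes[[i]])
    if (length(nd) != 2 || !is.numeric(nd))
      schemaError("node %d is not an [x, y] pair", i - 1L)
    xy[i, ] <- nd
  }

  # decode "ROLE:visibility" tag strings
  roles <- character(n); vis <- character(n)
  abbrev2role <- stats::setNames(names(roleAbbrev), roleAbbrev)
  for (i in seq_len(n)) {
    tg <- tags[[i]]
    parts <- strsplit(as.character(tg), ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% roleAbbrev ||
        !parts[2] %in% visibilityStates())
      schemaError("unknown tag string '%s' at node %d", as.character(tg), i - 1L)
    roles[i] <- abbrev2role[[parts[1]]]
    vis[i] <- parts[2]
  }

  trIdx <- vapply(doc$transitions, function(t) as.integer(t[[1]]), integer(1))
  if (any(trIdx < 0 | trIdx >= n))
    schemaError("transition index out of range")
  isTr <- seq_len(n) %in% (trIdx + 1L)
  if (any(isTr & roles != "transition"))
    schemaError("node listed in 'transitions' lacks the TR role tag")
  if (any(!isTr & roles == "transition"))
    schemaError("TR-tagged node not listed in 'transitions'")

  # adjacency from 0-based edge pairs
  adj <- vector("list", n)
  for (e in doc$edges) {
    ij <- unlist(e)
    if (length(ij) != 2 || any(ij < 0) || any(ij >= n))
      schemaError("edge [%s] references a nonexistent node",
                  paste(ij, collapse = ", "))
    i <- as.integer(ij[1]) + 1L; j <- as.integer(ij[2]) + 1L
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }

  # connected components (isolated nodes form their own)
  comp <- integer(n); nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    nc <- nc + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- nc
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }

  posesOut <- vector("list", nc)
  for (ci in seq_len(nc)) {
    members <- which(comp == ci)
    kpNodes <- members[roles[members] != "transition"]
    kpRolesHere <- roles[kpNodes]
    if (anyDuplicated(kpRolesHere))
      schemaError("duplicate role '%s' within one skeleton",
                  kpRolesHere[duplicated(kpRolesHere)][1])
    slotKp <- list(entry = NULL, hinge = NULL, tip1 = NULL, tip2 = NULL)
    node2role <- stats::setNames(kpRolesHere, kpNodes)
    for (k in kpNodes)
      slotKp[[roles[k]]] <- Keypoint(xy[k, 1], xy[k, 2], roles[k], vis[k])

    # contract transition chains: walk from each keypoint node through
    # consecutive transition nodes until another keypoint node is reached
    trans <- list(); transEdge <- character()
    seenPair <- character()
    for (k in kpNodes) {
      for (nb in adj[[k]]) {
        path <- integer(); prev <- k; cur <- nb
        while (roles[cur] == "transition") {
          path <- c(path, cur)
          nxt <- setdiff(adj[[cur]], prev)
          if (length(nxt) != 1L)
            schemaError("transition node %d must split exactly one edge",
                        cur - 1L)
          prev <- cur; cur <- nxt
        }
        ends <- sort(c(k, cur))
        key <- paste(ends, collapse = "-")
        if (key %in% seenPair) next
        seenPair <- c(seenPair, key)
        pair <- sort(match(roles[c(k, cur)],
                           c("entry", "hinge", "tip1", "tip2")))
        edgeName <- paste(c("entry", "hinge", "tip1", "tip2")[pair],
                          collapse = "-")
        if (!edgeName %in% chainEdges())
          schemaError("illegal skeleton edge %s-%s",
                      roleAbbrev[[roles[k]]], roleAbbrev[[roles[cur]]])
        # record transitions along the path in walk order from the 'k' side
        ordPath <- if (roles[k] == strsplit(edgeName, "-")[[1]][1]) path
                   else rev(path)
        for (t in ordPath) {
          trans <- c(trans, Keypoint(xy[t, 1], xy[t, 2], "transition", vis[t]))
          transEdge <- c(transEdge, edgeName)
        }
      }
    }
    posesOut[[ci]] <- ToolPose(
      entry = slotKp$entry, hinge = slotKp$hinge,
      tip1 = slotKp$tip1, tip2 = slotKp$tip2,
      transitions = trans, transitionEdges = transEdge,
      instanceId = ci
    )
  }

  extra <- doc[setdiff(names(doc), c("nodes", "tags", "edges", "transitions"))]
  FrameAnnotation(poses = posesOut, frameId = frameId,
                  width = width, height = height, extra = extra)
}

#' Serialize a FrameAnnotation to the per-frame JSON dialect
#'
#' The inverse of \code{\link{parseRawJson}}.  All four canonical slots are
#' written for every pose (missing ones as the (0, 0) sentinel with a
#' \code{:missing} tag) together with the three chain edges, so each pose is
#' one connected component; transition points split their edge.  Output key
#' order is deterministic, so serializing twice yields identical bytes.
#'
#' @param frame a valid \code{\linkS4class{FrameAnnotation}}.
#' @return A JSON string.
#' @export
serializeRawJson <- function(frame) {
  v <- validObject(frame, test = TRUE)
  if (!isTRUE(v))
    schemaError("serialization refused: %s", paste(v, collapse = "; "))
  nodes <- list(); tags <- list(); edges <- list(); transIdx <- list()
  slotNames <- c("entry", "hinge", "tip1", "tip2")
  ord <- order(vapply(frame@poses, function(p) p@instanceId, integer(1)))
  for (pose in frame@poses[ord]) {
    base <- length(nodes)  # 0-based index of this pose's first node
    sl <- poseSlots(pose)
    for (i in seq_along(slotNames)) {
      kp <- sl[[slotNames[i]]]
      nodes[[base + i]] <- c(kp@x, kp@y)
      tags[[base + i]] <- paste0(roleAbbrev[[kp@role]], ":", kp@tag)
    }
    slotIdx <- stats::setNames(base + seq_along(slotNames) - 1L, slotNames)
    tIdx <- integer(length(pose@transitions))
    for (i in seq_along(pose@transitions)) {
      kp <- pose@transitions[[i]]
      nodes[[length(nodes) + 1L]] <- c(kp@x, kp@y)
      tags[[length(tags) + 1L]] <- paste0("TR:", kp@tag)
      tIdx[i] <- length(nodes) - 1L
      transIdx[[length(transIdx) + 1L]] <- tIdx[i]
    }
    for (edge in chainEdges()) {
      ends <- strsplit(edge, "-", fixed = TRUE)[[1]]
      onEdge <- tIdx[pose@transitionEdges == edge]
      chain <- c(slotIdx[[ends[1]]], onEdge, slotIdx[[ends[2]]])
      for (i in seq_len(length(chain) - 1L))
        edges[[length(edges) + 1L]] <- c(chain[i], chain[i + 1L])
    }
  }
  doc <- c(list(nodes = nodes, tags = tags, edges = edges,
                transitions = transIdx),
           frame@extra)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
}

#' Read / write the per-frame dialect from disk
#'
#' @param path file path (conventionally \code{raw.json} inside a frame
#'   directory).
#' @param frame a \code{\linkS4class{FrameAnnotation}} (for writing).
#' @inheritParams parseRawJson
#' @return \code{readRawJson}: a \code{FrameAnnotation}; \code{writeRawJson}:
#'   the path, invisibly.
#' @export
readRawJson <- function(path, width = 960, height = 540,
                        frameId = basename(dirname(path))) {
  if (!file.exists(path)) parseError("no such file: %s", path)
  parseRawJson(paste(readLines(path, warn = FALSE), collapse = "\n"),
               width = width, height = height, frameId = frameId)
}

#' @rdname readRawJson
#' @export
writeRawJson <- function(frame, path) {
  writeLines(serializeRawJson(frame), path)
  invisible(path)
}
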