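#' Layout configuration
#'
#' Tunables of the 2D layout: \code{lambda} weights the squared deviation
#' from the starting layout against the projection stress; \code{maxIter}
#' and \code{tol} control the gradient-descent optimizer (stop when the
#' relative objective change drops below \code{tol}); \code{minOverlap} is
#' the minimum shared-label fraction for reusing a previously computed
#' member's layout as the start; \code{primaryThreshold},
#' \code{pairingCutoff} and \code{detection} are passed through to the
#' stats, sheet and detection stages. \code{seed} fixes any optional random
#' restarts (none are used by default; the pipeline is deterministic).
#'
#' @param lambda deviation-penalty weight (>= 0).
#' @param primaryThreshold see \code{\link{computeFamilyStats}}.
#' @param maxIter optimizer iteration cap.
#' @param tol relative-change convergence tolerance (> 0).
#' @param seed integer seed.
#' @param minOverlap fraction in [0, 1].
#' @param pairingCutoff see \code{\link{pairStrands}}.
#' @param detection see \code{\link{detectionParams}}.
#' @return Named list of settings.
#' @export
layoutConfig <- function(lambda = 0.05, primaryThreshold = 0.5,
                         maxIter = 2000L, tol = 1e-8, seed = 1L,
                         minOverlap = 0.5, pairingCutoff = 5.5,
                         detection = detectionParams()) {
  stopifnot(lambda >= 0, tol > 0, maxIter >= 1)
  list(lambda = lambda, primaryThreshold = primaryThreshold,
       maxIter = as.integer(maxIter), tol = tol, seed = as.integer(seed),
       minOverlap = minOverlap, pairingCutoff = pairingCutoff,
       detection = detection)
}

#' 3D anchor points of the layout elements
#'
#' A helix is anchored at its axis midpoint; a sheet at the centroid of its
#' member strands' axis midpoints. Pairwise distances between these anchors
#' are what the 2D layout tries to reproduce.
#'
#' @param sseTab annotated SSE table of one member.
#' @param sheets named list of \linkS4class{SheetModel} for that member.
#' @return Matrix (elements x 3) with rownames = element labels (helix
#'   labels and sheet ids).
#' @export
elementAnchors3d <- function(sseTab, sheets) {
  labs <- character(); pts <- NULL
  hx <- which(sseTab$type == "helix")
  for (i in hx) {
    labs <- c(labs, sseTab$label[i])
    pts <- rbind(pts, .sseMidpoint(sseTab, i))
  }
  for (id in names(sheets)) {
    rows <- match(sheets[[id]]@strandLabels, sseTab$label)
    mids <- do.call(rbind, lapply(rows, function(i) .sseMidpoint(sseTab, i)))
    labs <- c(labs, id)
    pts <- rbind(pts, colMeans(mids))
  }
  if (is.null(pts)) pts <- matrix(numeric(), 0, 3)
  rownames(pts) <- labs
  pts
}

.pairDists <- function(m) {
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- NULL
  d
}

#' Projection stress of a 2D placement
#'
#' Sum over unordered element pairs of the squared difference between the 2D
#' inter-element distance and the 3D inter-anchor distance, plus
#' \code{lambda} times the squared displacement from the starting layout for
#' the labels the start covers. With \code{lambda = 0} the value is
#' invariant under any rigid transform of all positions.
#'
#' @param positions elements x 2 matrix, rownames = labels.
#' @param anchors elements x 3 matrix from \code{\link{elementAnchors3d}}
#'   (same label set).
#' @param start optional matrix (subset of labels) x 2 of start positions.
#' @param lambda deviation weight.
#' @return Nonnegative scalar.
#' @examples
#' a <- rbind(A = c(0, 0, 0), B = c(10, 0, 0))
#' p <- rbind(A = c(0, 0), B = c(7, 0))
#' layoutStress(p, a)  # (10 - 7)^2 = 9
#' @export
layoutStress <- function(positions, anchors, start = NULL, lambda = 0) {
  if (!setequal(rownames(positions), rownames(anchors)))
    usageError("positions and anchors must cover the same labels")
  anchors <- anchors[rownames(positions), , drop = FALSE]
  dd <- .pairDists(positions) - .pairDists(anchors)
  s <- sum(dd[upper.tri(dd)]^2)
  if (!is.null(start) && lambda > 0) {
    shared <- intersect(rownames(start), rownames(positions))
    if (length(shared))
      s <- s + lambda * sum((positions[shared, , drop = FALSE] -
                             start[shared, , drop = FALSE])^2)
  }
  s
}

#' Kruskal-style normalized stress of a diagram
#'
#' \code{sqrt(sum (d2D - d3D)^2 / sum d3D^2)} over element pairs: 0 for a
#' perfect distance-preserving projection, dimensionless, comparable across
#' domains of different size.
#'
#' @param diagram a \linkS4class{DomainDiagram}.
#' @return Scalar in [0, Inf); 0 when fewer than 2 elements.
#' @export
normalizedStress <- function(diagram) {
  el <- diagramElements(diagram)
  if (nrow(el) < 2L) return(0)
  anchors <- elementAnchors3d(diagram@sseTable, diagram@sheets)
  pos <- cbind(el$x, el$y)
  rownames(pos) <- el$label
  anchors <- anchors[el$label, , drop = FALSE]
  num <- sum((.pairDists(pos) - .pairDists(anchors))[upper.tri(diag(nrow(pos)))]^2)
  den <- sum(.pairDists(anchors)[upper.tri(diag(nrow(pos)))]^2)
  if (den == 0) return(0)
  sqrt(num / den)
}

#' Choose a starting layout among previously computed diagrams
#'
#' Returns the computed diagram whose element labels overlap the new
#' domain's the most (ties to the smaller domain id), provided the shared
#' fraction |shared| / |domain labels| reaches \code{minOverlap}; otherwise
#' NULL (a fresh layout will be computed).
#'
#' @param domainLabels element labels of the domain about to be laid out.
#' @param computed named list of \linkS4class{DomainDiagram}.
#' @param minOverlap minimum shared fraction.
#' @return \code{list(diagram, shared)} or NULL.
#' @export
selectStartingLayout <- function(domainLabels, computed, minOverlap = 0.5) {
  if (!length(computed) || !length(domainLabels)) return(NULL)
  ids <- sort(names(computed))
  best <- NULL; bestRatio <- -1
  for (id in ids) {
    shared <- intersect(domainLabels, diagramElements(computed[[id]])$label)
    ratio <- length(shared) / length(domainLabels)
    if (ratio > bestRatio + 1e-12) {
      bestRatio <- ratio
      best <- list(diagram = computed[[id]], shared = shared)
    }
  }
  if (bestRatio >= minOverlap) best else NULL
}

# proper 2D rotation aligning A onto B (paired rows), returning the map
# x -> R (x - centA) + centB
.align2d <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  if (nrow(A) < 2L) {
    R <- diag(2)
  } else {
    H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u))); if (d == 0) d <- 1
    R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  }
  list(R = R, ca = ca, cb = cb,
       map = function(x) sweep(sweep(x, 2, ca) %*% t(R), 2, cb, "+"))
}

#' Initial 2D positions for the layout optimizer
#'
#' Labels covered by the starting layout take its coordinates exactly. The
#' remaining labels take the best-fit-plane (principal-plane) projection of
#' their 3D anchors; when a started subset exists, that projection is
#' rigidly rotated/translated onto the start via the shared labels before
#' the uncovered labels are read off. For coplanar anchors and no start the
#' projection reproduces every pairwise 3D distance exactly.
#'
#' @param anchors elements x 3 anchor matrix (rownames = labels).
#' @param start optional start-position matrix (subset of labels) x 2.
#' @param frameAnchors anchors defining the projection plane (default: all;
#'   the layout pipeline passes the primary anchors, so secondary elements
#'   never tilt the frame).
#' @return elements x 2 matrix of positions; attribute \code{"frame"} holds
#'   the projection frame (\code{origin}, \code{ex}, \code{ey} and the 2D
#'   rotation applied), used later to project 3D axis directions for angles.
#' @export
initialPositions <- function(anchors, start = NULL, frameAnchors = anchors) {
  labs <- rownames(anchors)
  fr <- planeFrame(frameAnchors)
  proj <- cbind(as.vector(sweep(anchors, 2, fr$origin) %*% fr$ex),
                as.vector(sweep(anchors, 2, fr$origin) %*% fr$ey))
  rownames(proj) <- labs
  rot <- diag(2)
  pos <- proj
  if (!is.null(start)) {
    shared <- intersect(labs, rownames(start))
    if (length(shared)) {
      al <- .align2d(proj[shared, , drop = FALSE],
                     start[shared, , drop = FALSE])
      pos <- al$map(proj)
      rot <- al$R
      pos[shared, ] <- start[shared, , drop = FALSE]
    }
  }
  attr(pos, "frame") <- list(origin = fr$origin, ex = fr$ex, ey = fr$ey,
                             rot = rot)
  pos
}

# gradient-descent with backtracking (Armijo) line search on the selected
# pair terms; only rows with active=TRUE move. Deterministic.
.descend <- function(pos, D, pairMask, active, start, lambda, maxIter, tol) {
  n <- nrow(pos)
  sIdx <- if (is.null(start)) integer() else
    which(rownames(pos) %in% rownames(start))
  sMat <- matrix(0, n, 2)
  if (length(sIdx))
    sMat[sIdx, ] <- start[rownames(pos)[sIdx], , drop = FALSE]
  obj <- function(P) {
    d <- .pairDists(P)
    v <- sum(((d - D)[pairMask & upper.tri(d)])^2)
    if (lambda > 0 && length(sIdx))
      v <- v + lambda * sum((P[sIdx, , drop = FALSE] -
                             sMat[sIdx, , drop = FALSE])^2)
    v
  }
  grad <- function(P) {
    G <- matrix(0, n, 2)
    d <- .pairDists(P)
    for (i in which(active)) {
      js <- which(pairMask[i, ] & seq_len(n) != i)
      for (j in js) {
        if (d[i, j] < 1e-12) next
        G[i, ] <- G[i, ] + 2 * (d[i, j] - D[i, j]) *
          (P[i, ] - P[j, ]) / d[i, j]
      }
      if (lambda > 0 && i %in% sIdx)
        G[i, ] <- G[i, ] + 2 * lambda * (P[i, ] - sMat[i, ])
    }
    G
  }
  f0 <- obj(pos)
  trace <- f0
  alpha <- 1
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    G <- grad(pos)
    gn2 <- sum(G^2)
    if (gn2 < 1e-20) { converged <- TRUE; break }
    step <- alpha
    accepted <- FALSE
    for (bt in 1:60) {
      cand <- pos
      cand[active, ] <- pos[active, ] - step * G[active, , drop = FALSE]
      f1 <- obj(cand)
      if (f1 <= f0 - 1e-4 * step * gn2) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }  # no descent direction left
    pos <- cand
    alpha <- min(step * 2, 1e3)
    trace <- c(trace, f1)
    if (f0 - f1 <= tol * max(f0, 1e-300)) { f0 <- f1; converged <- TRUE; break }
    f0 <- f1
  }
  attr(pos, "objective") <- f0
  attr(pos, "trace") <- trace
  attr(pos, "converged") <- converged
  pos
}

#' Two-stage placement of primary then secondary elements
#'
#' Stage 1 minimizes the projection stress over the primary elements only
#' (secondary elements excluded from the objective). Stage 2 freezes the
#' primaries and minimizes over the secondary elements, with every pair term
#' involving at least one secondary element active. The optimizer is a
#' deterministic gradient descent with backtracking line search from the
#' \code{\link{initialPositions}} initialization; the objective never
#' increases across iterations. If the iteration cap is hit before the
#' relative change drops below tolerance, the best iterate is returned and a
#' warning is recorded in the attribute \code{"warnings"}.
#'
#' @param anchors elements x 3 anchor matrix.
#' @param classes named character ("primary"/"secondary") covering all
#'   labels.
#' @param start optional start-position matrix.
#' @param config a \code{\link{layoutConfig}}.
#' @return elements x 2 position matrix with attributes \code{"frame"},
#'   \code{"objective"}, \code{"trace"} and \code{"warnings"}.
#' @export
placeElements <- function(anchors, classes, start = NULL,
                          config = layoutConfig()) {
  labs <- rownames(anchors)
  if (!all(labs %in% names(classes)))
    usageError("classes must cover every element label")
  primLabs <- labs[classes[labs] == "primary"]
  frameAnchors <- if (length(primLabs))
    anchors[primLabs, , drop = FALSE] else anchors
  pos <- initialPositions(anchors, start, frameAnchors)
  frame <- attr(pos, "frame")
  D <- .pairDists(anchors)
  prim <- labs[classes[labs] == "primary"]
  sec <- setdiff(labs, prim)
  warnings <- character()
  trace <- numeric()
  lambda <- if (is.null(start)) 0 else config$lambda
  n <- length(labs)
  if (length(prim) >= 1L) {
    mask <- outer(labs %in% prim, labs %in% prim, "&")
    out <- .descend(pos, D, mask, labs %in% prim, start, lambda,
                    config$maxIter, config$tol)
    trace <- c(trace, attr(out, "trace"))
    if (!attr(out, "converged"))
      warnings <- c(warnings, "primary placement hit the iteration cap")
    pos[] <- out
  }
  if (length(sec) >= 1L) {
    isSec <- labs %in% sec
    mask <- outer(isSec, isSec, "|")
    out <- .descend(pos, D, mask, isSec, start, lambda,
                    config$maxIter, config$tol)
    trace <- c(trace, attr(out, "trace"))
    if (!attr(out, "converged"))
      warnings <- c(warnings, "secondary placement hit the iteration cap")
    pos[] <- out
  }
  if (n == 1L) pos[1L, ] <- c(0, 0)
  attr(pos, "frame") <- frame
  attr(pos, "objective") <- layoutStress(pos, anchors, start, lambda)
  attr(pos, "trace") <- trace
  attr(pos, "warnings") <- warnings
  pos
}

# ---- angle handling ---------------------------------------------------------

# corners of the glyph rectangle of an element
.glyphRect <- function(x, y, angle, len, wid) {
  c1 <- cos(angle); s1 <- sin(angle)
  hx <- len / 2; hy <- wid / 2
  corners <- rbind(c(-hx, -hy), c(hx, -hy), c(hx, hy), c(-hx, hy))
  t(apply(corners, 1, function(p)
    c(x + c1 * p[1] - s1 * p[2], y + s1 * p[1] + c1 * p[2])))
}

.polyArea <- function(p) {
  if (is.null(p) || nrow(p) < 3L) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clip of convex polygon subj by convex polygon clip
.polyClip <- function(subj, clip) {
  out <- subj
  m <- nrow(clip)
  for (k in seq_len(m)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    a <- clip[k, ]; b <- clip[k %% m + 1L, ]
    e <- b - a
    side <- function(p) e[1] * (p[2] - a[2]) - e[2] * (p[1] - a[1])
    res <- NULL
    n <- nrow(out)
    for (i in seq_len(n)) {
      P <- out[i, ]; Q <- out[i %% n + 1L, ]
      sp <- side(P); sq <- side(Q)
      if (sp >= -1e-12) res <- rbind(res, P)
      if ((sp > 1e-12 && sq < -1e-12) || (sp < -1e-12 && sq > 1e-12)) {
        t <- sp / (sp - sq)
        res <- rbind(res, P + t * (Q - P))
      }
    }
    out <- res
  }
  out
}

.rectOverlapArea <- function(r1, r2) .polyArea(.polyClip(r1, r2))

.elementWidth <- function(type, nStrands = 1L, spacing = .SHEET_SPACING) {
  if (type == "helix") 3.0 else (nStrands - 1L) * spacing + 2.0
}

#' Assign and refine element angles
#'
#' The raw angle of each element is the in-plane orientation of its 3D axis
#' direction (helix axis; for a sheet, the direction-sign-weighted mean of
#' its strands' N-to-C axes, so antiparallel partners reinforce instead of
#' cancelling) projected into the frame used by
#' \code{\link{initialPositions}}. If any two glyph rectangles then overlap,
#' each element is rotated by up to +-15 degrees in 5-degree steps (sweep in
#' lexicographic label order, candidates ordered by |delta|) choosing the
#' rotation that minimizes the total pairwise overlap area. A zero-length
#' projected axis falls back to angle 0 with a recorded warning.
#'
#' @param elements data.frame with \code{label}, \code{type}, \code{length}
#'   and strand counts \code{nStrands} per element.
#' @param axisDirs elements x 3 matrix of 3D axis directions (rownames =
#'   labels).
#' @param positions elements x 2 positions with the \code{"frame"}
#'   attribute.
#' @return Named numeric vector of angles in [-pi, pi); attribute
#'   \code{"warnings"}.
#' @export
adjustAngles <- function(elements, axisDirs, positions) {
  frame <- attr(positions, "frame")
  labs <- elements$label
  warnings <- character()
  ang <- vapply(labs, function(l) {
    v <- axisDirs[l, ]
    p <- c(sum(v * frame$ex), sum(v * frame$ey))
    p <- as.vector(frame$rot %*% p)
    if (.norm2(p) < 1e-9) {
      warnings <<- c(warnings,
                     sprintf("element %s: axis perpendicular to plane", l))
      return(0)
    }
    atan2(p[2], p[1])
  }, numeric(1))
  ang <- .wrapAngle(ang)
  names(ang) <- labs
  wid <- vapply(seq_len(nrow(elements)), function(i)
    .elementWidth(elements$type[i], elements$nStrands[i]), numeric(1))
  rects <- function(a) lapply(seq_along(labs), function(i)
    .glyphRect(positions[labs[i], 1], positions[labs[i], 2], a[i],
               elements$length[i], wid[i]))
  totalOverlap <- function(rs) {
    tot <- 0
    n <- length(rs)
    if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      tot <- tot + .rectOverlapArea(rs[[i]], rs[[j]])
    tot
  }
  if (length(labs) > 1L && totalOverlap(rects(ang)) > 1e-9) {
    deltas <- c(0, -5, 5, -10, 10, -15, 15) * pi / 180
    for (i in order(labs)) {
      base <- ang
      scores <- vapply(deltas, function(d) {
        a <- base; a[i] <- .wrapAngle(base[i] + d)
        totalOverlap(rects(a))
      }, numeric(1))
      ang[i] <- .wrapAngle(base[i] + deltas[which.min(scores)])
    }
  }
  attr(ang, "warnings") <- warnings
  ang
}

# ---- orchestration ----------------------------------------------------------

# per-element metadata for one member
.elementInfo <- function(sseTab, sheets, stats) {
  st <- statsTable(stats)
  cls <- function(lab) {
    i <- match(lab, st$label)
    if (is.na(i)) "secondary" else st$class[i]
  }
  rows <- list(); dirs <- NULL; labs <- character()
  for (i in which(sseTab$type == "helix")) {
    lab <- sseTab$label[i]
    rows[[length(rows) + 1L]] <- data.frame(
      label = lab, type = "helix",
      length = sseTab$nRes[i] * .HELIX_UNIT, members = "",
      class = cls(lab), nStrands = 1L, stringsAsFactors = FALSE)
    labs <- c(labs, lab)
    dirs <- rbind(dirs, .sseDir(sseTab, i))
  }
  for (id in names(sheets)) {
    sh <- sheets[[id]]
    ridx <- match(sh@strandLabels, sseTab$label)
    # sign-weighted mean strand direction: antiparallel partners reinforce
    d <- colSums(do.call(rbind, lapply(seq_along(ridx), function(k)
      sh@template$sign[k] * .sseDir(sseTab, ridx[k]))))
    if (.norm2(d) < 1e-9) d <- .sseDir(sseTab, ridx[1L])
    classes <- vapply(sh@strandLabels, cls, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      label = id, type = "sheet",
      length = max(sh@template$length),
      members = paste(sh@strandLabels, collapse = ","),
      class = if (any(classes == "primary")) "primary" else "secondary",
      nStrands = length(ridx), stringsAsFactors = FALSE)
    labs <- c(labs, id)
    dirs <- rbind(dirs, .unit(d))
  }
  info <- do.call(rbind, rows)
  rownames(dirs) <- labs
  list(info = info, dirs = dirs)
}

#' Lay out one domain in 2D
#'
#' Orchestrates the per-domain pipeline: starting-layout selection among the
#' previously computed diagrams, 3D anchors, principal-plane initialization,
#' primary placement, primary angle adjustment, secondary placement,
#' secondary angle adjustment. Records the final objective value as the
#' diagram's stress. Deterministic for a fixed config.
#'
#' @param structure the member's \linkS4class{DomainStructure}.
#' @param sseTab its annotated SSE table.
#' @param sheets its sheet models (\code{\link{buildSheetsForMember}}).
#' @param stats family statistics (\code{\link{computeFamilyStats}}).
#' @param computed named list of already-computed
#'   \linkS4class{DomainDiagram} (starting-layout candidates).
#' @param config a \code{\link{layoutConfig}}.
#' @return A \linkS4class{DomainDiagram}.
#' @export
layoutDomain <- function(structure, sseTab, sheets, stats,
                         computed = list(), config = layoutConfig()) {
  ei <- .elementInfo(sseTab, sheets, stats)
  info <- ei$info
  if (is.null(info) || nrow(info) == 0L)
    return(new("DomainDiagram", domainId = domainId(structure),
               elements = data.frame(label = character(), type = character(),
                                     x = numeric(), y = numeric(),
                                     angle = numeric(), length = numeric(),
                                     members = character(),
                                     class = character(),
                                     stringsAsFactors = FALSE),
               sheets = list(), sseTable = sseTab,
               sequenceOrder = character(), stress = 0,
               frame = diag(3), warnings = character()))
  anchors <- elementAnchors3d(sseTab, sheets)
  anchors <- anchors[info$label, , drop = FALSE]
  sel <- selectStartingLayout(info$label, computed, config$minOverlap)
  start <- NULL
  if (!is.null(sel)) {
    se <- diagramElements(sel$diagram)
    start <- cbind(se$x, se$y)
    rownames(start) <- se$label
    start <- start[sel$shared, , drop = FALSE]
  }
  classes <- stats::setNames(info$class, info$label)
  pos <- placeElements(anchors, classes, start, config)
  warnings <- attr(pos, "warnings")
  angles <- adjustAngles(info, ei$dirs, pos)
  warnings <- c(warnings, attr(angles, "warnings"))
  el <- data.frame(label = info$label, type = info$type,
                   x = pos[info$label, 1], y = pos[info$label, 2],
                   angle = as.numeric(angles[info$label]),
                   length = info$length, members = info$members,
                   class = info$class,
                   stringsAsFactors = FALSE, row.names = NULL)
  lambda <- if (is.null(start)) 0 else config$lambda
  new("DomainDiagram",
      domainId = domainId(structure),
      elements = el,
      sheets = sheets,
      sseTable = sseTab,
      sequenceOrder = sseTab$label,
      stress = layoutStress(pos, anchors, start, lambda),
      frame = rbind(attr(pos, "frame")$ex, attr(pos, "frame")$ey,
                    attr(pos, "frame")$origin),
      warnings = if (is.null(warnings)) character() else warnings)
}

#' Lay out every member of a family
#'
#' Members are processed in deterministic order (descending SSE count, then
#' domain id); each may reuse an earlier member's diagram as its starting
#' layout, which keeps the family's diagrams in one shared frame and makes
#' them intercomparable.
#'
#' @param family an \linkS4class{AnnotatedFamily}.
#' @param stats its \linkS4class{FamilyStats}.
#' @param config a \code{\link{layoutConfig}}.
#' @return Named list of \linkS4class{DomainDiagram} (input member order).
#' @examples
#' fam <- makeFamily(familySpec(mixedRecipe(), nMembers = 3, seed = 11))
#' af <- annotateStructures(fam$familyId,
#'                          lapply(fam$members, `[[`, "structure"))
#' stats <- computeFamilyStats(af)
#' diags <- layoutFamily(af, stats)
#' diagramStress(diags[[1]])
#' @export
layoutFamily <- function(family, stats, config = layoutConfig()) {
  ids <- memberIds(family)
  nSSE <- vapply(ids, function(m) nrow(sseTable(family, m)), integer(1))
  ord <- ids[order(-nSSE, ids)]
  computed <- list()
  for (id in ord) {
    tab <- sseTable(family, id)
    sheets <- buildSheetsForMember(memberStructure(family, id), tab,
                                   config$pairingCutoff)
    computed[[id]] <- layoutDomain(memberStructure(family, id), tab, sheets,
                                   stats, computed, config)
  }
  computed[ids]
}
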