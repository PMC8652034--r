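# order-preserving, type-constrained alignment of member SSEs to reference
# SSEs. score(r, m) = maxDist - ||midpoint_r - T(midpoint_m)||, only for
# equal types and distances <= maxDist; gap penalty 0. Returns an integer
# vector (attribute "score" = total DP score): for each member SSE the
# matched reference row (NA = unmatched).
.dpMatchSSEs <- function(refTab, movTab, fit, maxDist = 10) {
  nr <- nrow(refTab); nm <- nrow(movTab)
  if (nr == 0L || nm == 0L) return(rep(NA_integer_, nm))
  sc <- matrix(-Inf, nm, nr)
  for (i in seq_len(nm)) {
    midm <- .applyRigid(.sseMidpoint(movTab, i), fit)
    for (j in seq_len(nr)) {
      if (movTab$type[i] != refTab$type[j]) next
      d <- .norm2(midm - .sseMidpoint(refTab, j))
      if (d <= maxDist) sc[i, j] <- maxDist - d
    }
  }
  # F[i+1, j+1] = best score aligning mov[1..i] with ref[1..j]
  F <- matrix(0, nm + 1L, nr + 1L)
  for (i in seq_len(nm)) for (j in seq_len(nr)) {
    best <- max(F[i, j + 1L], F[i + 1L, j])
    if (is.finite(sc[i, j])) best <- max(best, F[i, j] + sc[i, j])
    F[i + 1L, j + 1L] <- best
  }
  match <- rep(NA_integer_, nm)
  i <- nm; j <- nr
  while (i > 0L && j > 0L) {
    if (is.finite(sc[i, j]) &&
        abs(F[i + 1L, j + 1L] - (F[i, j] + sc[i, j])) < 1e-12 &&
        sc[i, j] > 0) {
      match[i] <- j; i <- i - 1L; j <- j - 1L
    } else if (F[i + 1L, j + 1L] == F[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  attr(match, "score") <- F[nm + 1L, nr + 1L]
  match
}

# superposition on a candidate SSE correspondence (pairs truncated to equal
# length per pair); NULL when under-determined
.fitFromPairs <- function(refTab, refXYZ, movTab, movXYZ, pairs) {
  refPts <- NULL; movPts <- NULL
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$mov[k]; j <- pairs$ref[k]
    len <- min(refTab$endIdx[j] - refTab$startIdx[j],
               movTab$endIdx[i] - movTab$startIdx[i]) + 1L
    refPts <- rbind(refPts, refXYZ[refTab$startIdx[j] + seq_len(len) - 1L, ,
                                   drop = FALSE])
    movPts <- rbind(movPts, movXYZ[movTab$startIdx[i] + seq_len(len) - 1L, ,
                                   drop = FALSE])
  }
  if (is.null(refPts) || nrow(refPts) < 3L) return(NULL)
  tryCatch(superpose(refPts, movPts), error = function(e) NULL)
}

# superposition of member onto reference on all C-alpha, truncated to the
# shorter length (no sequence alignment needed for same-family folds)
.roughFit <- function(refXYZ, movXYZ) {
  n <- min(nrow(refXYZ), nrow(movXYZ))
  superpose(refXYZ[seq_len(n), , drop = FALSE],
            movXYZ[seq_len(n), , drop = FALSE])
}

.sseCa <- function(structure, tab, rows) {
  do.call(rbind, lapply(rows, function(i)
    structure@coords[tab$startIdx[i]:tab$endIdx[i], , drop = FALSE]))
}

#' Cross-annotate SSEs so equivalent elements share labels family-wide
#'
#' Chooses a reference member (most SSEs, ties to the lexicographically
#' smallest domain id) and names its elements H1, H2, ... / E1, E2, ... by
#' per-type counters in sequence order. Every other member is rigidly
#' superposed onto the reference (all C-alpha truncated to equal length,
#' refined once on matched-SSE C-alpha) and its SSEs are aligned to the
#' reference by order-preserving, type-constrained dynamic programming with
#' a spatial midpoint-proximity score; pairs farther than \code{maxDist}
#' after superposition are forbidden. Matched SSEs inherit the reference
#' label; unmatched ones get fresh labels suffixed with the member id so
#' labels stay globally unique.
#'
#' @param familyId family identifier.
#' @param members named list; each element is a
#'   \code{list(structure = DomainStructure, sses = detectSSEs output)}.
#' @param maxDist forbid matches beyond this midpoint distance (Angstrom).
#' @return An \linkS4class{AnnotatedFamily}.
#' @examples
#' fam <- makeFamily(familySpec(hairpinRecipe(), nMembers = 2,
#'                              jitterSigma = 0, seed = 1))
#' mem <- lapply(fam$members, function(m)
#'   list(structure = m$structure, sses = detectSSEs(m$structure)))
#' af <- annotateFamily(fam$familyId, mem)
#' sseTable(af, memberIds(af)[1])$label
#' @export
annotateFamily <- function(familyId, members, maxDist = 10) {
  if (length(members) == 0L) usageError("family has no members")
  ids <- names(members)
  if (is.null(ids) || any(!nzchar(ids))) usageError("members must be named")
  nSSE <- vapply(members, function(m) nrow(m$sses), integer(1))
  # reference = the member closest to the family's consensus architecture,
  # taken as the per-type upper-quartile element count: robust against a
  # fragmented detection shifting the naming (fragments are rare outliers)
  # while still favouring full coverage when many members miss an element.
  # Ties go to the member with more SSEs, then the smallest id.
  nH <- vapply(members, function(m) sum(m$sses$type == "helix"), numeric(1))
  nE <- vapply(members, function(m) sum(m$sses$type == "strand"), numeric(1))
  q75 <- function(x) stats::quantile(x, 0.75, type = 1, names = FALSE)
  dev <- abs(nH - q75(nH)) + abs(nE - q75(nE))
  refId <- ids[order(dev, -nSSE, ids)][1L]
  refTab <- members[[refId]]$sses
  refXYZ <- members[[refId]]$structure@coords
  # reference naming: per-type counters in sequence order
  counters <- c(helix = 0L, strand = 0L)
  refTab$label <- vapply(seq_len(nrow(refTab)), function(i) {
    t <- refTab$type[i]
    counters[[t]] <<- counters[[t]] + 1L
    paste0(if (t == "helix") "H" else "E", counters[[t]])
  }, character(1))

  sses <- list(); structures <- list()
  structures[[refId]] <- members[[refId]]$structure
  sses[[refId]] <- refTab
  for (id in setdiff(ids, refId)) {
    tab <- members[[id]]$sses
    xyz <- members[[id]]$structure@coords
    if (nrow(tab) == 0L) {
      structures[[id]] <- members[[id]]$structure
      sses[[id]] <- tab
      next
    }
    # candidate initial superpositions: all C-alpha truncated to equal
    # length, plus shift-seeded SSE correspondences (member element i to
    # reference element i + s, same type), which handle members missing
    # leading or internal elements. Each candidate is scored by the DP
    # objective after one refinement on its matched-SSE C-alpha.
    fits <- list(.roughFit(refXYZ, xyz))
    nr <- nrow(refTab); nm <- nrow(tab)
    for (s in setdiff(seq(-(nm - 1L), nr - 1L), 0L)) {
      ref_i <- seq_len(nm) + s
      okp <- which(ref_i >= 1L & ref_i <= nr)
      okp <- okp[tab$type[okp] == refTab$type[ref_i[okp]]]
      if (!length(okp)) next
      f <- .fitFromPairs(refTab, refXYZ, tab, xyz,
                         data.frame(mov = okp, ref = ref_i[okp]))
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
    match <- NULL; bestScore <- -Inf
    for (fit in fits) {
      m0 <- .dpMatchSSEs(refTab, tab, fit, maxDist)
      hit <- which(!is.na(m0))
      if (length(hit)) {
        f2 <- .fitFromPairs(refTab, refXYZ, tab, xyz,
                            data.frame(mov = hit, ref = m0[hit]))
        if (!is.null(f2)) m0 <- .dpMatchSSEs(refTab, tab, f2, maxDist)
      }
      sc <- attr(m0, "score")
      if (sc > bestScore + 1e-9) { bestScore <- sc; match <- m0 }
    }
    lab <- rep(NA_character_, nrow(tab))
    lab[!is.na(match)] <- refTab$label[match[!is.na(match)]]
    # fresh member-unique labels for unmatched elements
    extra <- c(helix = sum(refTab$type == "helix"),
               strand = sum(refTab$type == "strand"))
    for (i in which(is.na(lab))) {
      t <- tab$type[i]
      extra[[t]] <- extra[[t]] + 1L
      lab[i] <- paste0(if (t == "helix") "H" else "E", extra[[t]], "_", id)
    }
    tab$label <- lab
    structures[[id]] <- members[[id]]$structure
    sses[[id]] <- tab
  }
  AnnotatedFamily(familyId, structures[ids], sses[ids])
}

#' Detect and annotate a family in one call
#'
#' Convenience wrapper: runs \code{\link{detectSSEs}} on every structure and
#' feeds the results to \code{\link{annotateFamily}}.
#'
#' @param familyId family identifier.
#' @param structures named list of \linkS4class{DomainStructure}.
#' @param params \code{\link{detectionParams}}.
#' @param maxDist see \code{\link{annotateFamily}}.
#' @return An \linkS4class{AnnotatedFamily}.
#' @export
annotateStructures <- function(familyId, structures,
                               params = detectionParams(), maxDist = 10) {
  members <- lapply(structures, function(s)
    list(structure = s, sses = detectSSEs(s, params)))
  annotateFamily(familyId, members, maxDist)
}

#' Compare assigned labels with generator ground truth
#'
#' Maps every detected SSE of every member to the same-type ground-truth
#' elements it overlaps (by residue range); an element is recovered when its
#' assigned label is the label of one of those truth elements (a detection
#' that merges two truth elements may legitimately carry either label).
#' Detected elements overlapping no truth element are left out of the
#' comparison, and truth elements that were never detected count against
#' the detection rate but not the recovery rate. Recovery asks only of the
#' annotation: did each detected element inherit the label the generator
#' gave that piece of chain?
#'
#' @param family an \linkS4class{AnnotatedFamily}.
#' @param truth named list (per member) of ground-truth tables with columns
#'   \code{label}, \code{type}, \code{startIdx}, \code{endIdx} (as produced
#'   by \code{\link{makeFamily}}).
#' @return List with \code{nTruth}, \code{nDetected}, \code{nCompared},
#'   \code{nRecovered}, \code{recoveryRate} and \code{detectionRate}.
#' @export
labelRecovery <- function(family, truth) {
  nTruth <- 0L; nDetected <- 0L; nCompared <- 0L; nRecovered <- 0L
  truthHit <- 0L
  for (m in memberIds(family)) {
    tab <- sseTable(family, m)
    tr <- truth[[m]]
    nTruth <- nTruth + nrow(tr)
    nDetected <- nDetected + nrow(tab)
    hit <- logical(nrow(tr))
    for (i in seq_len(nrow(tab))) {
      ov <- pmin(tab$endIdx[i], tr$endIdx) - pmax(tab$startIdx[i], tr$startIdx) + 1L
      ov[tr$type != tab$type[i]] <- 0L
      if (all(ov <= 0L)) next
      hit[which.max(ov)] <- TRUE
      nCompared <- nCompared + 1L
      if (tab$label[i] %in% tr$label[ov > 0L]) nRecovered <- nRecovered + 1L
    }
    truthHit <- truthHit + sum(hit)
  }
  list(nTruth = nTruth, nDetected = nDetected, nCompared = nCompared,
       nRecovered = nRecovered,
       recoveryRate = if (nCompared) nRecovered / nCompared else NA_real_,
       detectionRate = if (nTruth) truthHit / nTruth else NA_real_)
}
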