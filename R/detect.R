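#' Detection thresholds for C-alpha-based SSE assignment
#'
#' The detector classifies residues from short-range C-alpha distances only
#' (P-SEA-style rules). Residue i is helix-like when d(i, i+2) falls in
#' \code{helixD2} and d(i, i+3) in \code{helixD3}; strand-like when
#' d(i, i+2) falls in \code{strandD2}. Runs of at least \code{minHelixRun}
#' helix-like (resp. \code{minStrandRun} strand-like) residues become SSEs;
#' helices win where the two classes overlap. Flag gaps of up to
#' \code{closeGap} residues inside a run are closed before run extraction,
#' so an isolated distance outlier does not split an element in two.
#'
#' The default windows are centred on the canonical C-alpha trace geometry
#' (helix d2 = 5.43, d3 = 5.05; extended-strand d2 = 6.60 Angstrom), with
#' widths that keep misassignment below a few percent at coordinate noise of
#' ~0.3 Angstrom.
#'
#' @param helixD2,helixD3,strandD2 length-2 numeric windows in Angstrom.
#' @param minHelixRun,minStrandRun minimum run lengths (residues).
#' @param closeGap close flag gaps up to this many residues inside a run.
#' @param smoothWin running-median window (in residues) applied to the
#'   distance profiles before thresholding; a constant (ideal) profile is
#'   unchanged, while single-window noise outliers are rejected.
#' @param maxGap chain-break distance passed to \code{\link{chainSegments}}.
#' @return A named list of thresholds.
#' @export
detectionParams <- function(helixD2 = c(4.8, 6.1), helixD3 = c(4.35, 5.75),
                            strandD2 = c(5.8, 7.4), minHelixRun = 4L,
                            minStrandRun = 3L, closeGap = 2L, smoothWin = 3L,
                            maxGap = 4.5) {
  list(helixD2 = helixD2, helixD3 = helixD3, strandD2 = strandD2,
       minHelixRun = as.integer(minHelixRun),
       minStrandRun = as.integer(minStrandRun),
       closeGap = as.integer(closeGap), smoothWin = as.integer(smoothWin),
       maxGap = maxGap)
}

# centred running median over up to `win` points: single-window outliers
# (noise, or an extreme turn value next to a short element) are rejected,
# while a constant (ideal) profile keeps its canonical distances
.smoothProfile <- function(v, win) {
  if (win <= 1L || length(v) < 2L) return(v)
  half <- (win - 1L) %/% 2L
  vapply(seq_along(v), function(i)
    stats::median(v[max(1L, i - half):min(length(v), i + half)]), numeric(1))
}

# fill FALSE gaps of length <= g that are flanked by TRUE runs
.closeGaps <- function(flag, g) {
  if (g < 1L) return(flag)
  r <- rle(flag)
  if (length(r$values) >= 3L)
    for (k in 2:(length(r$values) - 1L))
      if (!r$values[k] && r$lengths[k] <= g &&
          r$values[k - 1L] && r$values[k + 1L])
        r$values[k] <- TRUE
  inverse.rle(r)
}

.runs <- function(flag) {
  # list of (start, end) index pairs of TRUE runs
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) c(starts[k], ends[k]))
}

.emptySSETable <- function() {
  data.frame(label = character(), type = character(), chain = character(),
             startIdx = integer(), endIdx = integer(),
             startAuth = integer(), endAuth = integer(), nRes = integer(),
             ax1 = numeric(), ay1 = numeric(), az1 = numeric(),
             ax2 = numeric(), ay2 = numeric(), az2 = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect helices and strands from a C-alpha trace
#'
#' Classifies residues with the distance rules of
#' \code{\link{detectionParams}}, inside chain segments only (SSEs never span
#' a chain break), merges runs into maximal non-overlapping elements (helix
#' takes precedence over strand on overlap) and fits a total-least-squares
#' axis per element. The classification depends only on internal distances,
#' so it is invariant under rigid motion of the whole domain.
#'
#' @param domain a \linkS4class{DomainStructure} with >= 5 residues.
#' @param params thresholds from \code{\link{detectionParams}}.
#' @return SSE data.frame (see \linkS4class{AnnotatedFamily}) with
#'   \code{label} set to \code{NA}; rows in sequence order. A coil-only
#'   domain gives zero rows.
#' @examples
#' helix <- makeIdealHelix(12)
#' dom <- DomainStructure("synA01", "syn", rep("A", 12), 1:12, rep("", 12),
#'                        helix)
#' detectSSEs(dom)$type  # "helix"
#' @export
detectSSEs <- function(domain, params = detectionParams()) {
  xyz <- domain@coords
  n <- nrow(xyz)
  if (n < 5L) usageError("SSE detection needs >= 5 residues")
  seg <- chainSegments(domain, params$maxGap)
  helixFlag <- logical(n); strandFlag <- logical(n)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    ns <- length(idx)
    if (ns < 3L) next
    d2 <- .smoothProfile(
      sqrt(rowSums((xyz[idx[-(1:2)], , drop = FALSE] -
                    xyz[idx[seq_len(ns - 2L)], , drop = FALSE])^2)),
      params$smoothWin)
    strandFlag[idx[seq_len(ns - 2L)]] <-
      d2 >= params$strandD2[1] & d2 <= params$strandD2[2]
    if (ns >= 4L) {
      d3 <- .smoothProfile(
        sqrt(rowSums((xyz[idx[-(1:3)], , drop = FALSE] -
                      xyz[idx[seq_len(ns - 3L)], , drop = FALSE])^2)),
        params$smoothWin)
      j <- seq_len(ns - 3L)
      helixFlag[idx[j]] <- d2[j] >= params$helixD2[1] &
        d2[j] <= params$helixD2[2] &
        d3 >= params$helixD3[1] & d3 <= params$helixD3[2]
    }
    # close short flag gaps (never across a break: we are inside a segment)
    helixFlag[idx] <- .closeGaps(helixFlag[idx], params$closeGap)
    strandFlag[idx] <- .closeGaps(strandFlag[idx], params$closeGap)
  }
  # a flag at i is a window constraining residues i..i+3 (helix) or i..i+2
  # (strand); a run of flags covers [first, last + span]. Several
  # consecutive windows are required so that noisy windows (or turn-junction
  # chords, which can brush the helix windows) never create an element.
  hRun <- max(3L, params$minHelixRun - 3L)
  sRun <- max(2L, params$minStrandRun - 2L)
  covered <- logical(n)
  rows <- list()
  for (r in .runs(helixFlag)) {
    if (r[2] - r[1] + 1L < hRun) next
    a <- r[1]; b <- min(r[2] + 3L, n)
    if (b - a + 1L < params$minHelixRun) next
    rows[[length(rows) + 1L]] <- list(type = "helix", a = a, b = b)
    covered[a:b] <- TRUE
  }
  strandFlag[covered] <- FALSE             # helix wins on overlap
  for (r in .runs(strandFlag)) {
    if (r[2] - r[1] + 1L < sRun) next
    a <- r[1]; b <- min(r[2] + 2L, n)
    while (b > a && covered[b]) b <- b - 1L  # trim into helix coverage
    if (b - a + 1L < max(3L, params$minStrandRun)) next
    rows[[length(rows) + 1L]] <- list(type = "strand", a = a, b = b)
  }
  if (!length(rows)) return(.emptySSETable())
  ord <- order(vapply(rows, function(x) x$a, numeric(1)))
  rows <- rows[ord]
  out <- .emptySSETable()
  for (x in rows) {
    ax <- fitAxis(xyz[x$a:x$b, , drop = FALSE])
    out[nrow(out) + 1L, ] <- list(NA_character_, x$type,
                                  domain@resChain[x$a],
                                  x$a, x$b,
                                  domain@resSeq[x$a], domain@resSeq[x$b],
                                  x$b - x$a + 1L,
                                  ax$start[1], ax$start[2], ax$start[3],
                                  ax$end[1], ax$end[2], ax$end[3])
  }
  out
}

# axis endpoints of row i of an SSE table as a 2 x 3 matrix
.sseAxis <- function(tab, i) {
  rbind(c(tab$ax1[i], tab$ay1[i], tab$az1[i]),
        c(tab$ax2[i], tab$ay2[i], tab$az2[i]))
}

.sseMidpoint <- function(tab, i) colMeans(.sseAxis(tab, i))

.sseDir <- function(tab, i) {
  a <- .sseAxis(tab, i)
  .unit(a[2, ] - a[1, ])
}
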