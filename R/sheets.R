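.SHEET_SPACING <- 4.8   # template inter-strand spacing, display units
.STRAND_UNIT   <- 3.3   # display length per strand residue
.HELIX_UNIT    <- 1.5   # display length per helix residue

#' Pair spatially adjacent beta-strands
#'
#' Two strands are adjacent (form a ladder) when the mean nearest-C-alpha
#' distance between them — averaged over both directions — is at most
#' \code{cutoff}. Orientation is parallel when the dot product of their
#' N-to-C axis directions is nonnegative, antiparallel otherwise.
#'
#' @param domain the member's \linkS4class{DomainStructure}.
#' @param strands the strand rows of its SSE table (labels assigned).
#' @param cutoff pairing cutoff, Angstrom; typical ladders sit at 4.8-5.0.
#' @return data.frame with columns \code{a}, \code{b} (strand labels) and
#'   \code{orientation}; zero rows when nothing pairs.
#' @export
pairStrands <- function(domain, strands, cutoff = 5.5) {
  k <- nrow(strands)
  out <- data.frame(a = character(), b = character(),
                    orientation = character(), stringsAsFactors = FALSE)
  if (k < 2L) return(out)
  xyz <- lapply(seq_len(k), function(i)
    domain@coords[strands$startIdx[i]:strands$endIdx[i], , drop = FALSE])
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    D <- outer(rowSums(xyz[[i]]^2), rowSums(xyz[[j]]^2), "+") -
      2 * tcrossprod(xyz[[i]], xyz[[j]])
    D[D < 0] <- 0
    D <- sqrt(D)
    mnn <- (mean(apply(D, 1, min)) + mean(apply(D, 2, min))) / 2
    if (mnn <= cutoff) {
      par <- sum(.sseDir(strands, i) * .sseDir(strands, j)) >= 0
      out[nrow(out) + 1L, ] <- list(strands$label[i], strands$label[j],
                                    if (par) "parallel" else "antiparallel")
    }
  }
  out
}

#' Group paired strands into rigid sheet templates
#'
#' Connected components of the strand-pairing graph become sheets. A
#' component must be a simple path (each strand laddered to at most two
#' neighbours, no cycle): beta-barrels and bifurcated sheets are rejected
#' with an error naming the strands. The template places the strands of a
#' sheet as parallel segments in path order, spaced by \code{spacing},
#' lengths proportional to residue count, with direction signs propagated
#' from the first strand through the pair orientations. The path is
#' canonicalized to start at the end with the lexicographically smaller
#' label, so the template does not depend on input order.
#'
#' @param strands strand rows of an SSE table (labels assigned).
#' @param adjacency result of \code{\link{pairStrands}}.
#' @param spacing template inter-strand spacing (display units).
#' @return Named list of \linkS4class{SheetModel} (names = sheet ids "S1",
#'   "S2", ... in order of their smallest strand label).
#' @export
buildSheets <- function(strands, adjacency, spacing = .SHEET_SPACING) {
  labs <- strands$label
  if (length(labs) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    if (nrow(adjacency)) adjacency[, c("a", "b")] else
      data.frame(a = character(), b = character()),
    directed = FALSE,
    vertices = data.frame(name = labs))
  comp <- igraph::components(g)
  groups <- split(labs, comp$membership[labs])
  # deterministic sheet order: by smallest member label
  groups <- groups[order(vapply(groups, min, character(1)))]
  orient <- function(a, b) {
    hit <- which((adjacency$a == a & adjacency$b == b) |
                 (adjacency$a == b & adjacency$b == a))
    adjacency$orientation[hit[1L]]
  }
  out <- list()
  for (gi in seq_along(groups)) {
    members <- sort(groups[[gi]])
    deg <- igraph::degree(g, v = members)
    nE <- sum(adjacency$a %in% members)
    if (any(deg > 2L))
      unsupportedTopologyError(
        "bifurcated sheet (strand with >2 ladders): %s",
        paste(members, collapse = ", "))
    if (length(members) > 1L && nE >= length(members))
      unsupportedTopologyError("cyclic sheet (beta-barrel): %s",
                               paste(members, collapse = ", "))
    # path order: walk from the lexicographically smaller endpoint
    if (length(members) == 1L) {
      path <- members
    } else {
      endpoints <- sort(members[deg[members] == 1L])
      path <- endpoints[1L]
      repeat {
        nb <- setdiff(names(igraph::neighbors(g, path[length(path)])), path)
        if (!length(nb)) break
        path <- c(path, nb[1L])
      }
    }
    k <- length(path)
    oris <- if (k > 1L) vapply(seq_len(k - 1L), function(i)
      orient(path[i], path[i + 1L]), character(1)) else character()
    sgn <- integer(k); sgn[1L] <- 1L
    if (k > 1L) for (i in 2:k)
      sgn[i] <- if (oris[i - 1L] == "parallel") sgn[i - 1L] else -sgn[i - 1L]
    nres <- strands$nRes[match(path, strands$label)]
    template <- data.frame(
      label = path,
      ox = (seq_len(k) - (k + 1) / 2) * spacing,
      oy = 0,
      sign = sgn,
      length = nres * .STRAND_UNIT,
      stringsAsFactors = FALSE)
    id <- sprintf("S%d", gi)
    out[[id]] <- new("SheetModel", sheetId = id, strandLabels = path,
                     orientations = oris, template = template)
  }
  out
}

#' @describeIn buildSheets pair and group in one call from an annotated
#'   member's structure and SSE table.
#' @param domain the member's structure.
#' @param sseTab its full SSE table.
#' @param cutoff pairing cutoff (Angstrom).
#' @export
buildSheetsForMember <- function(domain, sseTab, cutoff = 5.5,
                                 spacing = .SHEET_SPACING) {
  strands <- sseTab[sseTab$type == "strand", , drop = FALSE]
  buildSheets(strands, pairStrands(domain, strands, cutoff), spacing)
}
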