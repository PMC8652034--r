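#' @import methods
NULL

.CATH_ID_RE <- "^.+[A-Za-z0-9][0-9]{2}$"

.checkDomainId <- function(domain_id, source_id) {
  # CATH-style id: <source><chain letter><2-digit domain number>
  nchar(domain_id) == nchar(source_id) + 3L &&
    startsWith(domain_id, source_id) &&
    grepl("^[A-Za-z0-9][0-9]{2}$", substring(domain_id, nchar(source_id) + 1L))
}

#' DomainStructure: ordered C-alpha trace of one protein domain
#'
#' Holds one residue record per C-alpha: chain id, author sequence number,
#' insertion code and the 3D coordinate. Residues are kept in file order
#' within each extraction range. Identity of a residue is the triple
#' (chain, author number, insertion code).
#'
#' @slot domainId CATH-style domain identifier, e.g. \code{"1orwB01"}.
#' @slot sourceId structure identifier the domain was cut from (PDB ID).
#' @slot resChain character vector, chain id per residue.
#' @slot resSeq integer vector, author residue numbers.
#' @slot resIns character vector, insertion codes (\code{""} when absent).
#' @slot coords numeric matrix (n x 3) of C-alpha coordinates in Angstrom.
#'
#' @exportClass DomainStructure
setClass("DomainStructure",
  representation(
    domainId = "character",
    sourceId = "character",
    resChain = "character",
    resSeq   = "integer",
    resIns   = "character",
    coords   = "matrix"
  )
)

setValidity("DomainStructure", function(object) {
  n <- nrow(object@coords)
  msg <- character()
  if (n == 0L) msg <- c(msg, "domain has no residues")
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be n x 3")
  if (!all(is.finite(object@coords))) msg <- c(msg, "non-finite coordinates")
  if (length(object@resChain) != n || length(object@resSeq) != n ||
      length(object@resIns) != n)
    msg <- c(msg, "residue annotation lengths differ from coordinate count")
  if (!.checkDomainId(object@domainId, object@sourceId))
    msg <- c(msg, sprintf("domainId '%s' is not sourceId + chain + 2 digits",
                          object@domainId))
  key <- paste(object@resChain, object@resSeq, object@resIns)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (chain, seq_number, insertion_code) residue")
  if (length(msg)) msg else TRUE
})

#' Construct a DomainStructure
#'
#' @param domainId CATH-style id (source + chain letter + two digits).
#' @param sourceId source structure id (prefix of \code{domainId}).
#' @param resChain,resSeq,resIns per-residue chain, author number, insertion
#'   code.
#' @param coords n x 3 C-alpha coordinate matrix (Angstrom).
#' @return A \linkS4class{DomainStructure}.
#' @examples
#' d <- DomainStructure("synA01", "syn", rep("A", 4), 1:4, rep("", 4),
#'                      cbind(0:3 * 3.8, 0, 0))
#' nResidues(d)
#' @export
DomainStructure <- function(domainId, sourceId, resChain, resSeq, resIns,
                            coords) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  new("DomainStructure", domainId = domainId, sourceId = sourceId,
      resChain = as.character(resChain), resSeq = as.integer(resSeq),
      resIns = as.character(resIns), coords = coords)
}

#' AnnotatedFamily: family members with labelled SSEs
#'
#' A set of domains from one family, each with its detected secondary
#' structure elements (SSEs). After annotation, topologically equivalent
#' SSEs carry the same label across members. Per member the SSEs are stored
#' as a data.frame with one row per element, in sequence (N to C) order,
#' with columns \code{label}, \code{type} ("helix"/"strand"), \code{chain},
#' \code{startIdx}, \code{endIdx} (1-based indices into the member's residue
#' list), \code{startAuth}, \code{endAuth} (author numbering), \code{nRes},
#' and axis endpoints \code{ax1,ay1,az1,ax2,ay2,az2} (total-least-squares
#' axis, N-to-C direction).
#'
#' @slot familyId family identifier (e.g. a CATH node "2.140.10.30").
#' @slot structures named list of \linkS4class{DomainStructure}.
#' @slot sses named list (same names) of SSE data.frames.
#'
#' @exportClass AnnotatedFamily
setClass("AnnotatedFamily",
  representation(
    familyId   = "character",
    structures = "list",
    sses       = "list"
  )
)

setValidity("AnnotatedFamily", function(object) {
  msg <- character()
  if (!identical(names(object@structures), names(object@sses)))
    msg <- c(msg, "structures and sses must share member names")
  if (length(object@structures) == 0L) msg <- c(msg, "family has no members")
  type_of <- list()
  for (m in names(object@sses)) {
    tab <- object@sses[[m]]
    if (!is.data.frame(tab)) { msg <- c(msg, "sses entries must be data.frames"); next }
    lab <- tab$label
    lab <- lab[!is.na(lab)]
    if (anyDuplicated(lab))
      msg <- c(msg, sprintf("member %s repeats a label", m))
    for (i in seq_len(nrow(tab))) {
      l <- tab$label[i]
      if (is.na(l)) next
      t0 <- type_of[[l]]
      if (is.null(t0)) type_of[[l]] <- tab$type[i]
      else if (!identical(t0, tab$type[i]))
        msg <- c(msg, sprintf("label %s has inconsistent sse type", l))
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

AnnotatedFamily <- function(familyId, structures, sses) {
  new("AnnotatedFamily", familyId = familyId, structures = structures,
      sses = sses)
}

#' FamilyStats: per-label occurrence statistics over a family
#'
#' @slot familyId family identifier.
#' @slot nMembers number of member domains.
#' @slot table data.frame with one row per label: \code{label}, \code{count},
#'   \code{frequency} (= count / nMembers), \code{avgLength} (mean residue
#'   count over occurrences), \code{type}, \code{class} ("primary" or
#'   "secondary").
#' @slot primaryThreshold the frequency cut (class is primary iff
#'   frequency >= threshold).
#'
#' @exportClass FamilyStats
setClass("FamilyStats",
  representation(
    familyId = "character",
    nMembers = "integer",
    table    = "data.frame",
    primaryThreshold = "numeric"
  )
)

setValidity("FamilyStats", function(object) {
  tab <- object@table
  msg <- character()
  if (nrow(tab)) {
    if (any(tab$count <= 0L | tab$count > object@nMembers))
      msg <- c(msg, "counts must lie in (0, nMembers]")
    if (any(abs(tab$frequency - tab$count / object@nMembers) > 1e-12))
      msg <- c(msg, "frequency must equal count / nMembers")
    want <- ifelse(tab$frequency >= object@primaryThreshold,
                   "primary", "secondary")
    if (!identical(as.character(tab$class), want))
      msg <- c(msg, "class must follow the primary threshold")
  }
  if (length(msg)) msg else TRUE
})

#' SheetModel: rigid 2D template of one beta-sheet
#'
#' Strands of a sheet in spatial (ladder) order, their pairwise orientations,
#' and a fixed local-frame template: each strand gets a centre offset, a
#' direction sign (+1 along the local y axis, -1 against it) and a display
#' length. The template is never deformed during layout; the sheet moves as
#' one rigid element.
#'
#' @slot sheetId sheet identifier (e.g. "S1").
#' @slot strandLabels strand labels in path order across the sheet.
#' @slot orientations "parallel"/"antiparallel" per adjacent pair
#'   (length = number of strands - 1).
#' @slot template data.frame: \code{label}, \code{ox}, \code{oy} (local
#'   offsets), \code{sign} (+1/-1), \code{length} (display units).
#'
#' @exportClass SheetModel
setClass("SheetModel",
  representation(
    sheetId      = "character",
    strandLabels = "character",
    orientations = "character",
    template     = "data.frame"
  )
)

setValidity("SheetModel", function(object) {
  msg <- character()
  k <- length(object@strandLabels)
  if (anyDuplicated(object@strandLabels)) msg <- c(msg, "duplicate strand label")
  if (length(object@orientations) != max(k - 1L, 0L))
    msg <- c(msg, "need one orientation per adjacent strand pair")
  if (!identical(object@template$label, object@strandLabels))
    msg <- c(msg, "template rows must follow strandLabels order")
  if (k > 1L) {
    sgn <- object@template$sign
    for (i in seq_len(k - 1L)) {
      same <- sgn[i] == sgn[i + 1L]
      if (object@orientations[i] == "parallel" && !same)
        msg <- c(msg, "parallel neighbours must share direction sign")
      if (object@orientations[i] == "antiparallel" && same)
        msg <- c(msg, "antiparallel neighbours must have opposite signs")
    }
  }
  if (length(msg)) msg else TRUE
})

#' DomainDiagram: the 2D layout of one domain
#'
#' Helices and sheets with 2D centres, angles and display lengths, plus the
#' N-to-C order of the underlying SSEs (strands individually) used to route
#' connectors, and the final value of the layout objective.
#'
#' @slot domainId domain identifier.
#' @slot elements data.frame: \code{label} (helix label or sheet id),
#'   \code{type} ("helix"/"sheet"), \code{x}, \code{y}, \code{angle}
#'   (radians in [-pi, pi)), \code{length} (display units), \code{members}
#'   (comma-joined strand labels for sheets, \code{""} for helices),
#'   \code{class} ("primary"/"secondary").
#' @slot sheets named list of \linkS4class{SheetModel} for the sheet elements.
#' @slot sseTable the member's annotated SSE table (see
#'   \linkS4class{AnnotatedFamily}).
#' @slot sequenceOrder SSE labels N to C.
#' @slot stress final objective value (see \code{\link{layoutStress}}).
#' @slot frame 3 x 3 matrix; rows are the projection-plane x axis, y axis and
#'   the plane centroid used to map 3D axes into the diagram frame.
#' @slot warnings character vector of layout warnings.
#'
#' @exportClass DomainDiagram
setClass("DomainDiagram",
  representation(
    domainId      = "character",
    elements      = "data.frame",
    sheets        = "list",
    sseTable      = "data.frame",
    sequenceOrder = "character",
    stress        = "numeric",
    frame         = "matrix",
    warnings      = "character"
  )
)

setValidity("DomainDiagram", function(object) {
  el <- object@elements
  msg <- character()
  if (nrow(el)) {
    if (!all(is.finite(el$x)) || !all(is.finite(el$y)) ||
        !all(is.finite(el$angle)))
      msg <- c(msg, "non-finite element geometry")
    if (any(el$length <= 0)) msg <- c(msg, "display lengths must be positive")
    if (any(el$angle < -pi - 1e-9 | el$angle >= pi + 1e-9))
      msg <- c(msg, "angles must lie in [-pi, pi)")
    if (anyDuplicated(el$label)) msg <- c(msg, "duplicate element label")
  }
  if (length(msg)) msg else TRUE
})

#' FamilyDiagram: frequency-weighted overlay of a family's layouts
#'
#' Per SSE label (strands individually): the mean 2D centre over the members
#' carrying the label, the circular-mean angle, a display length proportional
#' to the family-average residue count, and the occurrence frequency, which
#' the renderer maps one-to-one to fill opacity.
#'
#' @slot familyId family identifier.
#' @slot table data.frame: \code{label}, \code{type} ("helix"/"strand"),
#'   \code{x}, \code{y}, \code{angle}, \code{length}, \code{frequency}.
#'
#' @exportClass FamilyDiagram
setClass("FamilyDiagram",
  representation(familyId = "character", table = "data.frame")
)

setValidity("FamilyDiagram", function(object) {
  tab <- object@table
  if (nrow(tab) && any(tab$frequency < 0 | tab$frequency > 1))
    "frequencies must lie in [0, 1]" else TRUE
})
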