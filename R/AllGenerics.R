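#' Accessors for sse2d classes
#'
#' Small accessor generics: \code{domainId} and \code{familyId} return
#' identifiers; \code{nResidues} the residue count of a domain;
#' \code{caCoords} the n x 3 C-alpha coordinate matrix; \code{sseTable} the
#' per-member SSE table; \code{memberIds} the member names of a family;
#' \code{statsTable} the per-label statistics; \code{diagramElements} the 2D
#' element table; \code{diagramStress} the final layout objective.
#'
#' @param x an sse2d object.
#' @param member for \code{sseTable} on a family: which member.
#' @return See description; identifiers are length-1 character vectors.
#' @name accessors
#' @examples
#' d <- DomainStructure("synA01", "syn", rep("A", 4), 1:4, rep("", 4),
#'                      cbind(0:3 * 3.8, 0, 0))
#' domainId(d); nResidues(d)
NULL

#' @rdname accessors
#' @export
setGeneric("domainId", function(x) standardGeneric("domainId"))
#' @rdname accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))
#' @rdname accessors
#' @export
setGeneric("sseTable", function(x, member) standardGeneric("sseTable"))
#' @rdname accessors
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))
#' @rdname accessors
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))
#' @rdname accessors
#' @export
setGeneric("diagramElements", function(x) standardGeneric("diagramElements"))
#' @rdname accessors
#' @export
setGeneric("diagramStress", function(x) standardGeneric("diagramStress"))

#' @rdname accessors
setMethod("domainId", "DomainStructure", function(x) x@domainId)
#' @rdname accessors
setMethod("domainId", "DomainDiagram", function(x) x@domainId)
#' @rdname accessors
setMethod("familyId", "AnnotatedFamily", function(x) x@familyId)
#' @rdname accessors
setMethod("familyId", "FamilyStats", function(x) x@familyId)
#' @rdname accessors
setMethod("familyId", "FamilyDiagram", function(x) x@familyId)
#' @rdname accessors
setMethod("nResidues", "DomainStructure", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("caCoords", "DomainStructure", function(x) x@coords)
#' @rdname accessors
setMethod("memberIds", "AnnotatedFamily", function(x) names(x@structures))
#' @rdname accessors
setMethod("sseTable", "AnnotatedFamily",
          function(x, member) x@sses[[member]])
#' @rdname accessors
setMethod("sseTable", "DomainDiagram", function(x, member) x@sseTable)
#' @rdname accessors
setMethod("statsTable", "FamilyStats", function(x) x@table)
#' @rdname accessors
setMethod("diagramElements", "DomainDiagram", function(x) x@elements)
#' @rdname accessors
setMethod("diagramElements", "FamilyDiagram", function(x) x@table)
#' @rdname accessors
setMethod("diagramStress", "DomainDiagram", function(x) x@stress)

#' @describeIn accessors structure of one member
#' @export
memberStructure <- function(x, member) x@structures[[member]]

setMethod("show", "DomainStructure", function(object) {
  cat(sprintf("DomainStructure %s (%s): %d residues, chains %s\n",
              object@domainId, object@sourceId, nrow(object@coords),
              paste(unique(object@resChain), collapse = ",")))
})

setMethod("show", "AnnotatedFamily", function(object) {
  n_sse <- vapply(object@sses, nrow, integer(1))
  lab <- unlist(lapply(object@sses, function(t) t$label), use.names = FALSE)
  cat(sprintf("AnnotatedFamily %s: %d members, %d-%d SSEs, %d distinct labels\n",
              object@familyId, length(object@structures),
              min(n_sse), max(n_sse), length(unique(stats::na.omit(lab)))))
})

setMethod("show", "FamilyStats", function(object) {
  cat(sprintf("FamilyStats %s: %d members, %d labels (%d primary at >= %.2f)\n",
              object@familyId, object@nMembers, nrow(object@table),
              sum(object@table$class == "primary"), object@primaryThreshold))
})

setMethod("show", "SheetModel", function(object) {
  cat(sprintf("SheetModel %s: %s\n", object@sheetId,
              paste(object@strandLabels, collapse = " - ")))
})

setMethod("show", "DomainDiagram", function(object) {
  cat(sprintf("DomainDiagram %s: %d elements, stress %.4g\n",
              object@domainId, nrow(object@elements), object@stress))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "FamilyDiagram", function(object) {
  cat(sprintf("FamilyDiagram %s: %d labels\n", object@familyId,
              nrow(object@table)))
})
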