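#' JSON interchange for annotations, statistics and layouts
#'
#' Annotation JSON is the substitution point for external SSE annotations:
#' \code{{"family": id, "members": {domain: [{"label","type","chain",
#' "start_auth","end_auth","axis_start","axis_end"}]}, "sheets": {domain:
#' [{"id","strands","orientations"}]}}}. Residue numbers are author
#' numbering; axes are Angstrom 3-vectors. Stats JSON carries
#' \code{{"family","n_members","labels": {label: {count,frequency,
#' avg_length,type,class}}}}; layout JSON \code{{"domain","stress",
#' "sequence","elements":[...],"sheets":[...]}}. All writers are
#' deterministic (fixed ordering, full-precision numbers), so identical
#' inputs give byte-identical files.
#'
#' @param family an \linkS4class{AnnotatedFamily}.
#' @param sheets optional named list (per member) of sheet-model lists.
#' @param path file to write or read.
#' @return Writers return \code{path} invisibly; readers return the
#'   reconstructed object.
#' @name annotationJSON
NULL

#' @rdname annotationJSON
#' @export
writeAnnotationJSON <- function(family, path, sheets = NULL) {
  members <- lapply(memberIds(family), function(m) {
    tab <- sseTable(family, m)
    lapply(seq_len(nrow(tab)), function(i) list(
      label = tab$label[i], type = tab$type[i], chain = tab$chain[i],
      start_auth = tab$startAuth[i], end_auth = tab$endAuth[i],
      axis_start = c(tab$ax1[i], tab$ay1[i], tab$az1[i]),
      axis_end = c(tab$ax2[i], tab$ay2[i], tab$az2[i])))
  })
  names(members) <- memberIds(family)
  doc <- list(family = familyId(family), members = members)
  if (!is.null(sheets)) {
    doc$sheets <- lapply(sheets, function(sl)
      lapply(sl, function(s) list(id = s@sheetId,
                                  strands = as.list(s@strandLabels),
                                  orientations = as.list(s@orientations))))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname annotationJSON
#' @param structures named list of \linkS4class{DomainStructure} used to map
#'   author numbering back to residue indices.
#' @export
readAnnotationJSON <- function(path, structures) {
  doc <- jsonlite::read_json(path)
  ids <- names(doc$members)
  if (!all(ids %in% names(structures)))
    usageError("annotation members missing from supplied structures")
  sses <- list()
  for (m in ids) {
    s <- structures[[m]]
    rows <- doc$members[[m]]
    tab <- .emptySSETable()
    for (r in rows) {
      a <- which(s@resChain == r$chain & s@resSeq == r$start_auth)[1L]
      b <- which(s@resChain == r$chain & s@resSeq == r$end_auth)[1L]
      if (is.na(a) || is.na(b))
        usageError("annotation range %s-%s not in structure %s",
                   r$start_auth, r$end_auth, m)
      tab[nrow(tab) + 1L, ] <- list(
        r$label, r$type, r$chain, a, b, r$start_auth, r$end_auth,
        b - a + 1L,
        r$axis_start[[1]], r$axis_start[[2]], r$axis_start[[3]],
        r$axis_end[[1]], r$axis_end[[2]], r$axis_end[[3]])
    }
    sses[[m]] <- tab
  }
  AnnotatedFamily(doc$family, structures[ids], sses)
}

#' @rdname annotationJSON
#' @param stats a \linkS4class{FamilyStats}.
#' @export
writeStatsJSON <- function(stats, path) {
  tab <- statsTable(stats)
  labels <- lapply(seq_len(nrow(tab)), function(i) list(
    count = tab$count[i], frequency = tab$frequency[i],
    avg_length = tab$avgLength[i], type = tab$type[i],
    class = tab$class[i]))
  names(labels) <- tab$label
  jsonlite::write_json(
    list(family = familyId(stats), n_members = stats@nMembers,
         primary_threshold = stats@primaryThreshold, labels = labels),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname annotationJSON
#' @export
readStatsJSON <- function(path) {
  doc <- jsonlite::read_json(path)
  labs <- names(doc$labels)
  tab <- data.frame(
    label = labs,
    count = vapply(doc$labels, function(l) as.integer(l$count), integer(1)),
    frequency = vapply(doc$labels, function(l) as.numeric(l$frequency),
                       numeric(1)),
    avgLength = vapply(doc$labels, function(l) as.numeric(l$avg_length),
                       numeric(1)),
    type = vapply(doc$labels, function(l) l$type, character(1)),
    class = vapply(doc$labels, function(l) l$class, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  new("FamilyStats", familyId = doc$family,
      nMembers = as.integer(doc$n_members), table = tab,
      primaryThreshold = as.numeric(doc$primary_threshold))
}

#' @rdname annotationJSON
#' @param diagram a \linkS4class{DomainDiagram}.
#' @export
writeLayoutJSON <- function(diagram, path) {
  el <- diagramElements(diagram)
  elements <- lapply(seq_len(nrow(el)), function(i) list(
    label = el$label[i], type = el$type[i], x = el$x[i], y = el$y[i],
    angle_deg = el$angle[i] * 180 / pi, length = el$length[i],
    members = el$members[i], class = el$class[i]))
  sheets <- lapply(diagram@sheets, function(s) list(
    id = s@sheetId, strands = as.list(s@strandLabels),
    orientations = as.list(s@orientations),
    template = lapply(seq_len(nrow(s@template)), function(k) list(
      label = s@template$label[k], ox = s@template$ox[k],
      oy = s@template$oy[k], sign = s@template$sign[k],
      length = s@template$length[k]))))
  jsonlite::write_json(
    list(domain = domainId(diagram), stress = diagram@stress,
         sequence = as.list(diagram@sequenceOrder),
         elements = elements, sheets = unname(sheets)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname annotationJSON
#' @export
readLayoutJSON <- function(path) {
  doc <- jsonlite::read_json(path)
  el <- doc$elements
  elements <- data.frame(
    label = vapply(el, function(e) e$label, character(1)),
    type = vapply(el, function(e) e$type, character(1)),
    x = vapply(el, function(e) as.numeric(e$x), numeric(1)),
    y = vapply(el, function(e) as.numeric(e$y), numeric(1)),
    angle = vapply(el, function(e) as.numeric(e$angle_deg), numeric(1)) *
      pi / 180,
    length = vapply(el, function(e) as.numeric(e$length), numeric(1)),
    members = vapply(el, function(e) e$members, character(1)),
    class = vapply(el, function(e) e$class, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  sheets <- list()
  for (s in doc$sheets) {
    tpl <- s$template
    template <- data.frame(
      label = vapply(tpl, function(t) t$label, character(1)),
      ox = vapply(tpl, function(t) as.numeric(t$ox), numeric(1)),
      oy = vapply(tpl, function(t) as.numeric(t$oy), numeric(1)),
      sign = vapply(tpl, function(t) as.integer(t$sign), integer(1)),
      length = vapply(tpl, function(t) as.numeric(t$length), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    sheets[[s$id]] <- new("SheetModel", sheetId = s$id,
                          strandLabels = unlist(s$strands),
                          orientations = as.character(unlist(s$orientations)),
                          template = template)
  }
  new("DomainDiagram", domainId = doc$domain, elements = elements,
      sheets = sheets, sseTable = .emptySSETable(),
      sequenceOrder = as.character(unlist(doc$sequence)),
      stress = as.numeric(doc$stress), frame = diag(3),
      warnings = character())
}
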