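#' Per-label occurrence statistics over a family
#'
#' For every SSE label: the number of members carrying it, the occurrence
#' frequency (count / number of members, exactly), the arithmetic-mean
#' residue count over its occurrences, and the primary/secondary class
#' (primary iff frequency >= \code{primaryThreshold}).
#'
#' @param family an \linkS4class{AnnotatedFamily}.
#' @param primaryThreshold frequency cut for the primary class; the boundary
#'   value itself is primary.
#' @return A \linkS4class{FamilyStats}.
#' @examples
#' fam <- makeFamily(familySpec(hairpinRecipe(), nMembers = 4,
#'                              jitterSigma = 0, seed = 1))
#' af <- annotateStructures(fam$familyId,
#'                          lapply(fam$members, `[[`, "structure"))
#' statsTable(computeFamilyStats(af))
#' @export
computeFamilyStats <- function(family, primaryThreshold = 0.5) {
  ids <- memberIds(family)
  n <- length(ids)
  count <- list(); lens <- list(); type <- list()
  for (m in ids) {
    tab <- sseTable(family, m)
    if (nrow(tab) == 0L) next
    stopifnot(!anyDuplicated(tab$label))  # guarded by AnnotatedFamily validity
    for (i in seq_len(nrow(tab))) {
      l <- tab$label[i]
      count[[l]] <- (count[[l]] %||% 0L) + 1L
      lens[[l]] <- c(lens[[l]], tab$nRes[i])
      type[[l]] <- tab$type[i]
    }
  }
  labs <- names(count)
  # stable, human order: reference labels first (H1 < H2 < ... numerically)
  labs <- labs[order(!grepl("^[HE][0-9]+$", labs),
                     substr(labs, 1, 1),
                     suppressWarnings(as.integer(sub("^[HE]([0-9]+).*$", "\\1",
                                                     labs))),
                     labs)]
  cnt <- vapply(labs, function(l) count[[l]], integer(1))
  freq <- cnt / n
  tab <- data.frame(
    label = labs,
    count = cnt,
    frequency = freq,
    avgLength = vapply(labs, function(l) mean(lens[[l]]), numeric(1)),
    type = vapply(labs, function(l) type[[l]], character(1)),
    class = ifelse(freq >= primaryThreshold, "primary", "secondary"),
    stringsAsFactors = FALSE, row.names = NULL)
  new("FamilyStats", familyId = familyId(family), nMembers = as.integer(n),
      table = tab, primaryThreshold = primaryThreshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
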