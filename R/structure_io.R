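#' Read a macromolecular structure file into per-chain C-alpha records
#'
#' Parses a PDB or mmCIF file (via bio3d) and keeps one record per residue
#' that has a C-alpha atom. HETATM residues are dropped, alternate locations
#' are resolved to the highest-occupancy conformer (first wins on a tie), and
#' only the first model of a multi-model file is used. Residue identity is
#' (chain, author number, insertion code); records keep file order within
#' each chain.
#'
#' @param path file to read.
#' @param format \code{"pdb"}, \code{"mmcif"} or \code{"auto"} (by file
#'   extension: \code{.cif} / \code{.mmcif} read as mmCIF, anything else as
#'   PDB).
#' @return A named list, one element per chain id, each a data.frame with
#'   columns \code{chain}, \code{seq} (author numbering), \code{ins}
#'   (insertion code, \code{""} when absent), \code{x}, \code{y}, \code{z}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' d <- DomainStructure("synA01", "syn", rep("A", 4), 1:4, rep("", 4),
#'                      cbind(0:3 * 3.8, 0, 0))
#' writeMinimalPDB(d, pdb)
#' chains <- readStructure(pdb)
#' names(chains)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) ioError("cannot read structure file '%s'", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(suppressMessages(
      if (format == "pdb") bio3d::read.pdb(path, multi = FALSE,
                                           rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE)
    )),
    error = function(e) ioError("failed to parse '%s' as %s: %s",
                                path, format, conditionMessage(e))
  )
  atoms <- parsed$atom
  # first model only (read.pdb multi=FALSE already collapses; guard for cif)
  if (!is.null(atoms$type))
    atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  atoms <- atoms[!is.na(atoms$elety) & atoms$elety == "CA", , drop = FALSE]
  if (nrow(atoms) == 0L)
    emptyStructureError("no C-alpha ATOM records in '%s'", path)
  atoms$ins <- ifelse(is.na(atoms$insert), "", as.character(atoms$insert))
  atoms$chain <- ifelse(is.na(atoms$chain), "", as.character(atoms$chain))
  atoms$o <- ifelse(is.na(atoms$o), 1, as.numeric(atoms$o))
  # altloc: per residue keep the highest-occupancy CA, first on tie
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), factor(key, unique(key))),
                        function(idx) idx[which.max(atoms$o[idx])]),
                 use.names = FALSE)
  atoms <- atoms[sort(keep), , drop = FALSE]
  out <- lapply(split(atoms, factor(atoms$chain, unique(atoms$chain))),
                function(a) data.frame(chain = a$chain,
                                       seq = as.integer(a$resno),
                                       ins = a$ins,
                                       x = as.numeric(a$x),
                                       y = as.numeric(a$y),
                                       z = as.numeric(a$z),
                                       stringsAsFactors = FALSE,
                                       row.names = NULL))
  out
}

#' Cut a domain out of a parsed structure by chain + residue ranges
#'
#' Selects the residues whose (chain, author number) fall inside any of the
#' given ranges (inclusive at both ends, the CATH segment convention), in
#' range order then file order. Residues absent from the file are silently
#' skipped.
#'
#' @param chains result of \code{\link{readStructure}}.
#' @param domainId CATH-style domain id for the result.
#' @param ranges data.frame (or list coercible to one) with columns
#'   \code{chain}, \code{start}, \code{end} in author numbering.
#' @param sourceId source structure id; default: \code{domainId} minus its
#'   final chain + 2-digit suffix.
#' @return A \linkS4class{DomainStructure}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' d <- DomainStructure("synA01", "syn", rep("A", 10), 1:10, rep("", 10),
#'                      cbind(0:9 * 3.8, 0, 0))
#' writeMinimalPDB(d, pdb)
#' dom <- extractDomain(readStructure(pdb), "synA01",
#'                      data.frame(chain = "A", start = 3, end = 7))
#' nResidues(dom)  # 5
#' @export
extractDomain <- function(chains, domainId, ranges, sourceId = NULL) {
  ranges <- as.data.frame(ranges)
  if (!all(c("chain", "start", "end") %in% names(ranges)))
    usageError("ranges needs columns chain, start, end")
  if (any(ranges$start > ranges$end))
    usageError("range start must not exceed end")
  if (is.null(sourceId))
    sourceId <- substring(domainId, 1L, nchar(domainId) - 3L)
  picked <- list()
  for (i in seq_len(nrow(ranges))) {
    ch <- as.character(ranges$chain[i])
    tab <- chains[[ch]]
    if (is.null(tab)) next
    sel <- tab[tab$seq >= ranges$start[i] & tab$seq <= ranges$end[i], ,
               drop = FALSE]
    if (nrow(sel)) picked[[length(picked) + 1L]] <- sel
  }
  if (!length(picked))
    emptyDomainError("no residue of '%s' matches any range", domainId)
  res <- do.call(rbind, picked)
  DomainStructure(domainId, sourceId, res$chain, res$seq, res$ins,
                  cbind(res$x, res$y, res$z))
}

#' Write a DomainStructure as a minimal PDB file
#'
#' Emits one fixed-format ATOM record per residue (C-alpha only, residue type
#' ALA, occupancy 1.00). Coordinates are written at PDB precision (3
#' decimals), so a round trip preserves them to 1e-3 Angstrom.
#'
#' @param domain a \linkS4class{DomainStructure}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMinimalPDB <- function(domain, path) {
  xyz <- domain@coords
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(xyz)), substr(domain@resChain, 1, 1), domain@resSeq,
    ifelse(domain@resIns == "", " ", substr(domain@resIns, 1, 1)),
    xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Chain-break segmentation of a C-alpha trace
#'
#' Consecutive residues farther apart than \code{maxGap} (or on different
#' chains) start a new segment; secondary structure elements never span a
#' segment boundary.
#'
#' @param domain a \linkS4class{DomainStructure}.
#' @param maxGap maximum C-alpha to C-alpha distance (Angstrom) within a
#'   segment.
#' @return Integer vector of segment indices, one per residue.
#' @export
chainSegments <- function(domain, maxGap = 4.5) {
  xyz <- domain@coords
  n <- nrow(xyz)
  seg <- integer(n)
  s <- 1L
  seg[1L] <- s
  if (n > 1L) for (i in 2:n) {
    d <- sqrt(sum((xyz[i, ] - xyz[i - 1L, ])^2))
    if (d > maxGap || domain@resChain[i] != domain@resChain[i - 1L]) s <- s + 1L
    seg[i] <- s
  }
  seg
}
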