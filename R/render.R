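#' Rendering style for SVG diagrams
#'
#' Glyph vocabulary: helices are rounded rectangles, strands are arrows
#' pointing N to C (drawn per strand inside the rigid sheet template),
#' connectors are grey polylines joining consecutive SSEs. Layout
#' coordinates are mathematical (y up); the renderer flips y because SVG y
#' grows downward.
#'
#' @param helixFill,strandFill fill colors (CSS hex).
#' @param connectorColor connector stroke color.
#' @param helixWidth,strandWidth glyph widths in layout units.
#' @param scale pixels per layout unit (> 0).
#' @param padding canvas padding in pixels.
#' @param opacityFloor minimum fill-opacity in the family overlay (0 keeps
#'   opacity exactly equal to frequency).
#' @return Named list of style settings.
#' @export
renderStyle <- function(helixFill = "#d62728", strandFill = "#1f77b4",
                        connectorColor = "#888888", helixWidth = 3.0,
                        strandWidth = 2.0, scale = 6, padding = 20,
                        opacityFloor = 0) {
  stopifnot(scale > 0,
            grepl("^#[0-9a-fA-F]{6}$", helixFill),
            grepl("^#[0-9a-fA-F]{6}$", strandFill))
  list(helixFill = helixFill, strandFill = strandFill,
       connectorColor = connectorColor, helixWidth = helixWidth,
       strandWidth = strandWidth, scale = scale, padding = padding,
       opacityFloor = opacityFloor)
}

.fmt <- function(x) formatC(x, format = "f", digits = 3)

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# per-SSE-label world geometry of a diagram: center, angle (direction the
# glyph points), type, display length
.glyphGeometry <- function(diagram) {
  el <- diagramElements(diagram)
  out <- list()
  for (i in seq_len(nrow(el))) {
    if (el$type[i] == "helix") {
      out[[el$label[i]]] <- list(x = el$x[i], y = el$y[i],
                                 angle = el$angle[i], type = "helix",
                                 length = el$length[i])
    } else {
      sh <- diagram@sheets[[el$label[i]]]
      th <- el$angle[i]
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      tpl <- sh@template
      for (k in seq_len(nrow(tpl))) {
        off <- as.vector(R %*% c(tpl$ox[k], tpl$oy[k]))
        out[[tpl$label[k]]] <- list(
          x = el$x[i] + off[1], y = el$y[i] + off[2],
          angle = .wrapAngle(if (tpl$sign[k] > 0) th else th + pi),
          type = "strand", length = tpl$length[k], sign = tpl$sign[k],
          sheet = el$label[i])
      }
    }
  }
  out
}

.helixGlyph <- function(label, x, y, angleDeg, len, wid, fill, opacity = 1) {
  sprintf(paste0(
    '<g id="%s" class="helix" transform="translate(%s,%s) rotate(%s)">',
    '<rect x="%s" y="%s" width="%s" height="%s" rx="%s" fill="%s"',
    ' fill-opacity="%s" stroke="#333333" stroke-width="0.5"/>',
    '<text x="0" y="0" text-anchor="middle" dominant-baseline="middle"',
    ' font-size="8">%s</text></g>'),
    .xmlEscape(label), .fmt(x), .fmt(y), .fmt(angleDeg),
    .fmt(-len / 2), .fmt(-wid / 2), .fmt(len), .fmt(wid), .fmt(wid / 3),
    fill, .fmt(opacity), .xmlEscape(label))
}

.strandGlyph <- function(label, x, y, angleDeg, len, wid, fill, sign,
                         opacity = 1) {
  h <- len / 2; w <- wid / 2; head <- min(0.35 * len, 2.4)
  pts <- sprintf("%s,%s %s,%s %s,%s %s,%s %s,%s %s,%s %s,%s",
                 .fmt(-h), .fmt(-w / 1.6), .fmt(h - head), .fmt(-w / 1.6),
                 .fmt(h - head), .fmt(-w), .fmt(h), "0.000",
                 .fmt(h - head), .fmt(w), .fmt(h - head), .fmt(w / 1.6),
                 .fmt(-h), .fmt(w / 1.6))
  sprintf(paste0(
    '<g id="%s" class="strand" data-sign="%d" ',
    'transform="translate(%s,%s) rotate(%s)">',
    '<polygon points="%s" fill="%s" fill-opacity="%s" stroke="#333333"',
    ' stroke-width="0.5"/>',
    '<text x="0" y="0" text-anchor="middle" dominant-baseline="middle"',
    ' font-size="8">%s</text></g>'),
    .xmlEscape(label), as.integer(sign), .fmt(x), .fmt(y), .fmt(angleDeg),
    pts, fill, .fmt(opacity), .xmlEscape(label))
}

.svgDoc <- function(width, height, body) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                        'version="1.1" width="%s" height="%s">\n'),
                 .fmt(width), .fmt(height)),
         paste(body, collapse = "\n"),
         if (length(body)) "\n" else "", "</svg>\n")
}

# world (layout units, y up) -> pixel transform given bounds
.pixelFrame <- function(xs, ys, lens, style) {
  pad <- style$padding / style$scale + max(c(lens, 1)) / 2 + 2
  x0 <- min(xs) - pad; x1 <- max(xs) + pad
  y0 <- min(ys) - pad; y1 <- max(ys) + pad
  list(toX = function(x) (x - x0) * style$scale,
       toY = function(y) (y1 - y) * style$scale,
       width = (x1 - x0) * style$scale, height = (y1 - y0) * style$scale)
}

#' Render one domain diagram as SVG text
#'
#' One glyph group per element (helices directly; each strand drawn inside
#' its sheet's rigid template transformed by the sheet's center and angle),
#' each carrying its label as both the group id and a text node; straight
#' connectors with a single midpoint offset join consecutive SSEs in
#' sequence order. A pure function of (diagram, style): repeated calls give
#' byte-identical output.
#'
#' @param diagram a \linkS4class{DomainDiagram}.
#' @param style a \code{\link{renderStyle}}.
#' @return Length-1 character: an SVG 1.1 document.
#' @export
renderDomainSVG <- function(diagram, style = renderStyle()) {
  geo <- .glyphGeometry(diagram)
  if (!length(geo)) return(.svgDoc(2 * style$padding, 2 * style$padding,
                                   character()))
  xs <- vapply(geo, `[[`, numeric(1), "x")
  ys <- vapply(geo, `[[`, numeric(1), "y")
  lens <- vapply(geo, `[[`, numeric(1), "length")
  fr <- .pixelFrame(xs, ys, lens, style)
  body <- character()
  seqOrd <- diagram@sequenceOrder[diagram@sequenceOrder %in% names(geo)]
  if (length(seqOrd) > 1L) for (i in seq_len(length(seqOrd) - 1L)) {
    a <- geo[[seqOrd[i]]]; b <- geo[[seqOrd[i + 1L]]]
    mx <- (a$x + b$x) / 2; my <- (a$y + b$y) / 2
    d <- c(b$x - a$x, b$y - a$y)
    nrm <- sqrt(sum(d^2))
    off <- if (nrm > 1e-9) 0.8 * c(-d[2], d[1]) / nrm else c(0.8, 0)
    body <- c(body, sprintf(
      '<polyline class="connector" points="%s,%s %s,%s %s,%s" fill="none" stroke="%s" stroke-width="1"/>',
      .fmt(fr$toX(a$x)), .fmt(fr$toY(a$y)),
      .fmt(fr$toX(mx + off[1])), .fmt(fr$toY(my + off[2])),
      .fmt(fr$toX(b$x)), .fmt(fr$toY(b$y)), style$connectorColor))
  }
  for (lab in names(geo)) {
    g <- geo[[lab]]
    # y flip reverses the sense of rotation
    aDeg <- -g$angle * 180 / pi
    px <- fr$toX(g$x); py <- fr$toY(g$y)
    body <- c(body, if (g$type == "helix")
      .helixGlyph(lab, px, py, aDeg, g$length * style$scale,
                  style$helixWidth * style$scale, style$helixFill)
    else
      .strandGlyph(lab, px, py, aDeg, g$length * style$scale,
                   style$strandWidth * style$scale, style$strandFill,
                   g$sign))
  }
  .svgDoc(fr$width, fr$height, body)
}

#' Frequency-weighted family overlay diagram
#'
#' For every SSE label (strands individually, located through their sheet's
#' template in each member): the arithmetic-mean 2D center over the members
#' that carry the label, the circular-mean angle, a display length
#' proportional to the family-average residue count, and the occurrence
#' frequency from the family statistics.
#'
#' @param diagrams named list of \linkS4class{DomainDiagram}.
#' @param stats the family's \linkS4class{FamilyStats}.
#' @return A \linkS4class{FamilyDiagram}.
#' @export
computeFamilyDiagram <- function(diagrams, stats) {
  if (!length(diagrams)) usageError("no diagrams given")
  st <- statsTable(stats)
  acc <- list()
  for (d in diagrams) {
    geo <- .glyphGeometry(d)
    for (lab in names(geo)) {
      g <- geo[[lab]]
      acc[[lab]] <- rbind(acc[[lab]], c(g$x, g$y, g$angle))
    }
  }
  labs <- intersect(st$label, names(acc))
  rows <- lapply(labs, function(lab) {
    i <- match(lab, st$label)
    unit <- if (st$type[i] == "helix") .HELIX_UNIT else .STRAND_UNIT
    m <- acc[[lab]]
    data.frame(label = lab, type = st$type[i],
               x = mean(m[, 1]), y = mean(m[, 2]),
               angle = circularMean(m[, 3]),
               length = st$avgLength[i] * unit,
               frequency = st$frequency[i],
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), type = character(), x = numeric(),
               y = numeric(), angle = numeric(), length = numeric(),
               frequency = numeric(), stringsAsFactors = FALSE)
  new("FamilyDiagram", familyId = familyId(stats), table = tab)
}

#' Render the family overlay as SVG text
#'
#' One glyph per label with \code{fill-opacity} equal to its occurrence
#' frequency (plus the style's optional legibility floor, 0 by default); no
#' connectors, since an averaged topology would be ambiguous.
#'
#' @param fam a \linkS4class{FamilyDiagram}.
#' @param style a \code{\link{renderStyle}}.
#' @return Length-1 character: an SVG 1.1 document.
#' @export
renderFamilySVG <- function(fam, style = renderStyle()) {
  tab <- fam@table
  if (!nrow(tab)) return(.svgDoc(2 * style$padding, 2 * style$padding,
                                 character()))
  fr <- .pixelFrame(tab$x, tab$y, tab$length, style)
  body <- character()
  for (i in seq_len(nrow(tab))) {
    op <- max(tab$frequency[i], style$opacityFloor)
    aDeg <- -tab$angle[i] * 180 / pi
    px <- fr$toX(tab$x[i]); py <- fr$toY(tab$y[i])
    body <- c(body, if (tab$type[i] == "helix")
      .helixGlyph(tab$label[i], px, py, aDeg, tab$length[i] * style$scale,
                  style$helixWidth * style$scale, style$helixFill, op)
    else
      .strandGlyph(tab$label[i], px, py, aDeg, tab$length[i] * style$scale,
                   style$strandWidth * style$scale, style$strandFill, 1L, op))
  }
  .svgDoc(fr$width, fr$height, body)
}
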