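library(xml2)

renderFixture <- function() memoFixture("renderfx", function() {
  dom <- makeDomain(mixedRecipe())$structure
  af <- annotateStructures("9.9.9.9", list(synA01 = dom))
  st <- computeFamilyStats(af)
  list(af = af, st = st, diag = layoutFamily(af, st)[[1]])
})

test_that("domain SVG has one glyph per element and parses as strict XML", {
  fx <- renderFixture()
  svg <- renderDomainSVG(fx$diag)
  doc <- read_xml(svg)  # strict parse
  helices <- xml_find_all(doc, "//*[@class='helix']")
  strands <- xml_find_all(doc, "//*[@class='strand']")
  expect_length(helices, 2L)  # mixed domain: 2 helices
  expect_length(strands, 2L)  # + 2 strands inside one sheet
  ids <- c(xml_attr(helices, "id"), xml_attr(strands, "id"))
  expect_false(anyDuplicated(ids) > 0)
  labs <- unlist(lapply(memberIds(fx$af),
                        function(m) sseTable(fx$af, m)$label))
  expect_setequal(ids, labs)
  # every glyph also carries its label as a text node
  for (id in ids)
    expect_equal(xml_text(xml_find_first(
      doc, sprintf("//*[@id='%s']/*[local-name()='text']", id))), id)
})

test_that("an empty diagram renders as a valid empty SVG", {
  empty <- new("DomainDiagram", domainId = "synZ01",
               elements = data.frame(label = character(), type = character(),
                                     x = numeric(), y = numeric(),
                                     angle = numeric(), length = numeric(),
                                     members = character(),
                                     class = character(),
                                     stringsAsFactors = FALSE),
               sheets = list(), sseTable = sse2d:::.emptySSETable(),
               sequenceOrder = character(), stress = 0, frame = diag(3),
               warnings = character())
  svg <- renderDomainSVG(empty)
  doc <- read_xml(svg)
  expect_length(xml_find_all(doc, "//*[@class='helix' or @class='strand']"),
                0L)
})

test_that("rendering is a pure function of diagram and style", {
  fx <- renderFixture()
  expect_identical(renderDomainSVG(fx$diag), renderDomainSVG(fx$diag))
  fd <- computeFamilyDiagram(setNames(list(fx$diag), "synA01"), fx$st)
  expect_identical(renderFamilySVG(fd), renderFamilySVG(fd))
})

test_that("the family diagram averages centers and wraps angles", {
  fx <- renderFixture()
  d1 <- fx$diag
  d2 <- d1
  e <- d2@elements
  e$x <- e$x + 2  # second member shifted
  d2@elements <- e
  fd <- computeFamilyDiagram(list(a = d1, b = d2), fx$st)
  tab <- diagramElements(fd)
  e1 <- diagramElements(d1)
  h <- e1$label[e1$type == "helix"][1]
  expect_equal(tab$x[tab$label == h], e1$x[e1$label == h] + 1)
  expect_equal(tab$frequency[tab$label == h], 1.0)

  # identical members reproduce the member geometry exactly
  fdSame <- computeFamilyDiagram(list(a = d1, b = d1), fx$st)
  expect_equal(diagramElements(fdSame)$x[tab$label == h],
               e1$x[e1$label == h])
})

test_that("overlay opacity equals occurrence frequency", {
  fx <- renderFixture()
  fd <- computeFamilyDiagram(setNames(list(fx$diag), "synA01"), fx$st)
  tab <- fd@table
  tab$frequency <- c(0.5, rep(1, nrow(tab) - 1L))
  fd@table <- tab
  doc <- read_xml(renderFamilySVG(fd))
  node <- xml_find_first(doc, sprintf("//*[@id='%s']", tab$label[1]))
  shape <- xml_find_first(node, "*[local-name()='rect' or local-name()='polygon']")
  expect_identical(xml_attr(shape, "fill-opacity"), "0.500")
  node2 <- xml_find_first(doc, sprintf("//*[@id='%s']", tab$label[2]))
  shape2 <- xml_find_first(node2, "*[local-name()='rect' or local-name()='polygon']")
  expect_identical(xml_attr(shape2, "fill-opacity"), "1.000")

  # empty family diagram still renders
  fd@table <- tab[0, ]
  expect_no_error(read_xml(renderFamilySVG(fd)))
})

test_that("antiparallel hairpin strands render with opposite arrows", {
  fam <- makeFamily(familySpec(hairpinRecipe(), nMembers = 1,
                               jitterSigma = 0, seed = 1))
  af <- annotateStructures(fam$familyId,
                           lapply(fam$members, `[[`, "structure"))
  st <- computeFamilyStats(af)
  d <- layoutFamily(af, st)[[1]]
  doc <- read_xml(renderDomainSVG(d))
  signs <- as.integer(xml_attr(xml_find_all(doc, "//*[@class='strand']"),
                               "data-sign"))
  expect_setequal(signs, c(-1L, 1L))
})
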