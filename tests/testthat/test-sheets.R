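# detect a recipe domain and give its strands sequence-order labels
labeledStrands <- function(recipe) {
  dom <- makeDomain(recipe)$structure
  tab <- detectSSEs(dom)
  tab$label <- paste0(ifelse(tab$type == "helix", "H", "E"),
                      ave(seq_len(nrow(tab)), tab$type, FUN = seq_along))
  list(dom = dom, tab = tab,
       strands = tab[tab$type == "strand", , drop = FALSE])
}

test_that("the hairpin pairs as one antiparallel ladder", {
  fx <- labeledStrands(hairpinRecipe())
  adj <- pairStrands(fx$dom, fx$strands)
  expect_equal(nrow(adj), 1L)
  expect_identical(adj$orientation, "antiparallel")
})

test_that("strands far apart do not pair", {
  rec <- hairpinRecipe()
  rec$ox[2] <- 15  # 15 A apart: beyond any ladder
  dom <- makeDomain(rec)$structure
  tab <- detectSSEs(dom)
  tab$label <- c("E1", "E2")
  expect_equal(nrow(pairStrands(dom, tab)), 0L)
})

test_that("a three-strand meander pairs only consecutive neighbours", {
  fx <- labeledStrands(meanderRecipe(3))
  adj <- pairStrands(fx$dom, fx$strands)
  pairs <- sort(paste(adj$a, adj$b))
  expect_equal(pairs, sort(c("E1 E2", "E2 E3")))
})

test_that("sheet templates respect spacing, order and direction signs", {
  fx <- labeledStrands(hairpinRecipe())
  sheets <- buildSheets(fx$strands, pairStrands(fx$dom, fx$strands))
  expect_length(sheets, 1L)
  sh <- sheets[[1]]
  tpl <- sh@template
  expect_equal(abs(diff(tpl$ox)), 4.8)
  expect_equal(sort(tpl$sign * c(1, 1)), c(-1, 1))  # antiparallel: opposite

  # singleton strand: trivial sheet
  solo <- fx$strands[1, , drop = FALSE]
  s1 <- buildSheets(solo, pairStrands(fx$dom, solo))
  expect_length(s1, 1L)
  expect_equal(nrow(s1[[1]]@template), 1L)
})

test_that("sign propagation matches brute force over orientation patterns", {
  # four strands on a path; enumerate all 2^3 orientation assignments and
  # check propagated signs against direct recursion
  labs <- c("E1", "E2", "E3", "E4")
  strands <- sse2d:::.emptySSETable()
  for (k in 1:4)
    strands[k, ] <- list(labs[k], "strand", "A", (k - 1L) * 10L + 1L,
                         (k - 1L) * 10L + 5L, (k - 1L) * 10L + 1L,
                         (k - 1L) * 10L + 5L, 5L,
                         k * 4.8, 0, 0, k * 4.8, 13.2, 0)
  for (bits in 0:7) {
    ori <- ifelse(bitwAnd(bits, 2^(0:2)) > 0, "parallel", "antiparallel")
    adj <- data.frame(a = labs[1:3], b = labs[2:4], orientation = ori,
                      stringsAsFactors = FALSE)
    sheets <- buildSheets(strands, adj)
    expect_length(sheets, 1L)
    sgn <- sheets[[1]]@template$sign
    want <- c(1L, integer(3))
    for (k in 2:4) want[k] <- if (ori[k - 1] == "parallel") want[k - 1] else
      -want[k - 1]
    expect_equal(sgn, want)
    # all-antiparallel means strictly alternating signs
    if (all(ori == "antiparallel")) expect_equal(sgn, c(1L, -1L, 1L, -1L))
  }
})

test_that("barrels and bifurcated sheets are rejected with strand names", {
  fx <- labeledStrands(barrelRecipe(6))
  adj <- pairStrands(fx$dom, fx$strands)
  expect_gte(nrow(adj), 6L)  # closed ring
  err <- expect_error(buildSheets(fx$strands, adj),
                      class = "unsupportedTopologyError")
  expect_match(conditionMessage(err), "E1")

  # bifurcation: a hub strand laddered to three partners
  labs <- c("E1", "E2", "E3", "E4")
  strands <- sse2d:::.emptySSETable()
  for (k in 1:4)
    strands[k, ] <- list(labs[k], "strand", "A", (k - 1L) * 10L + 1L,
                         (k - 1L) * 10L + 5L, (k - 1L) * 10L + 1L,
                         (k - 1L) * 10L + 5L, 5L,
                         k * 4.8, 0, 0, k * 4.8, 13.2, 0)
  adj2 <- data.frame(a = c("E1", "E1", "E1"), b = c("E2", "E3", "E4"),
                     orientation = "parallel", stringsAsFactors = FALSE)
  expect_error(buildSheets(strands, adj2),
               class = "unsupportedTopologyError")
})

test_that("sheets partition the strand labels and ignore input order", {
  fx <- labeledStrands(meanderRecipe(4))
  adj <- pairStrands(fx$dom, fx$strands)
  sheets <- buildSheets(fx$strands, adj)
  all1 <- sort(unname(unlist(lapply(sheets, function(s) s@strandLabels))))
  expect_equal(all1, sort(fx$strands$label))

  perm <- fx$strands[c(3, 1, 4, 2), , drop = FALSE]
  sheets2 <- buildSheets(perm, pairStrands(fx$dom, perm))
  expect_equal(lapply(sheets, function(s) s@template),
               lapply(sheets2, function(s) s@template))
})
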