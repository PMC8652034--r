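test_that("the ideal helix has canonical radius, spacing and axis", {
  h <- makeIdealHelix(10)
  expect_equal(sqrt(h[, 1]^2 + h[, 2]^2), rep(2.3, 10), tolerance = 1e-9)
  steps <- sqrt(rowSums(diff(h)^2))
  expect_equal(steps, rep(steps[1], 9), tolerance = 1e-9)
  expect_equal(steps[1], 3.83, tolerance = 0.02)
  expect_lt(acos(abs(sum(fitAxis(makeIdealHelix(18))$dir *
                           c(0, 0, 1)))) * 180 / pi, 5)
  # arbitrary direction is normalized silently
  h2 <- makeIdealHelix(10, direction = c(0, 0, 7))
  expect_equal(h2, h, tolerance = 1e-9)
})

test_that("the ideal strand is an extended zigzag that detects as strand", {
  s <- makeIdealStrand(7)
  i <- 1:5
  d2 <- sqrt(rowSums((s[i + 2, ] - s[i, ])^2))
  expect_equal(d2, rep(6.6, 5), tolerance = 1e-9)
  mids <- (s[1:6, ] + s[2:7, ]) / 2  # midline collinear along direction
  expect_lt(max(abs(mids[, 2:3])), 1e-9)
  dom <- domainFromCoords(rbind(s))
  expect_identical(detectSSEs(dom)$type, "strand")
})

test_that("makeDomain assembles SSEs with physical linkers and truth", {
  d <- makeDomain(mixedRecipe())
  steps <- sqrt(rowSums(diff(caCoords(d$structure))^2))
  expect_true(all(steps >= 2.8 & steps <= 4.2))
  expect_identical(d$truth$label, c("H1", "H2", "E1", "E2"))
  expect_error(makeDomain(mixedRecipe()[0, ]), class = "generationError")

  single <- makeDomain(hairpinRecipe()[1, ])
  expect_equal(nResidues(single$structure), 5L)  # no linker added

  clash <- hairpinRecipe(); clash$ox[2] <- 0.5  # strands on top of each other
  expect_error(makeDomain(clash), class = "generationError")
})

test_that("family generation is reproducible and respects the null case", {
  spec0 <- familySpec(hairpinRecipe(), nMembers = 3, jitterSigma = 0,
                      seed = 7)
  fam <- makeFamily(spec0)
  base <- caCoords(fam$members[[1]]$structure)
  for (m in fam$members)
    expect_equal(caCoords(m$structure), base, tolerance = 1e-12)
  fam2 <- makeFamily(spec0)
  expect_equal(lapply(fam$members, function(m) caCoords(m$structure)),
               lapply(fam2$members, function(m) caCoords(m$structure)))
  expect_match(names(fam$members)[1], "^syn[A-Z][0-9]{2}$")
})

test_that("deletions are governed by the per-member substreams", {
  spec <- familySpec(mixedRecipe(), nMembers = 8, jitterSigma = 0,
                     deletionProb = 0.25, seed = 13)
  fam <- makeFamily(spec)
  kept <- vapply(fam$members, function(m) nrow(m$truth), integer(1))
  # replay the generator's RNG discipline to predict the deletion pattern
  replay <- vapply(seq_len(spec$nMembers), function(m) {
    sub <- spec$seed * 1009L + m * 7919L
    sse2d:::.withSeed(sub, {
      keep <- if (m > 1L) stats::runif(nrow(spec$recipe)) >= spec$deletionProb
              else rep(TRUE, nrow(spec$recipe))
      if (!any(keep)) keep[1L] <- TRUE
      sum(keep)
    })
  }, integer(1))
  expect_equal(unname(kept), replay)
  # dropping a member leaves the others' geometry untouched
  spec2 <- familySpec(mixedRecipe(), nMembers = 7, jitterSigma = 0,
                      deletionProb = 0.25, seed = 13)
  fam2 <- makeFamily(spec2)
  for (m in names(fam2$members))
    expect_equal(caCoords(fam2$members[[m]]$structure),
                 caCoords(fam$members[[m]]$structure))
})

test_that("generated traces always keep physical consecutive spacing", {
  for (s in 1:3) {
    fam <- makeFamily(familySpec(randomDomainRecipe(6, 100 + s),
                                 nMembers = 3, jitterSigma = 0,
                                 deletionProb = 0.3, seed = s))
    for (m in fam$members) {
      steps <- sqrt(rowSums(diff(caCoords(m$structure))^2))
      expect_true(all(steps >= 2.8 & steps <= 4.2))
      # one sse_type per truth label
      expect_false(anyDuplicated(m$truth$label) > 0)
    }
  }
})

test_that("family specs validate their fields", {
  expect_error(familySpec(mixedRecipe(), nMembers = 0), class = "usageError")
  expect_error(familySpec(mixedRecipe(), jitterSigma = -1),
               class = "usageError")
  expect_error(familySpec(mixedRecipe(), deletionProb = 1),
               class = "usageError")
})

test_that("fixture export writes PDBs, ranges and truth JSON", {
  td <- tempfile()
  fam <- makeFamily(familySpec(hairpinRecipe(), nMembers = 2,
                               jitterSigma = 0, seed = 3))
  rangesPath <- writeFamilyFixture(fam, td)
  expect_true(file.exists(rangesPath))
  ranges <- readRangesTSV(rangesPath)
  expect_equal(nrow(ranges), 2L)
  doms <- lapply(seq_len(nrow(ranges)), function(i)
    extractDomain(readStructure(ranges$path[i]), ranges$domain[i],
                  ranges[i, c("chain", "start", "end")]))
  expect_equal(nResidues(doms[[1]]),
               nResidues(fam$members[[1]]$structure))
  truth <- jsonlite::read_json(file.path(td, "truth.json"))
  expect_named(truth$truth, names(fam$members))
})
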