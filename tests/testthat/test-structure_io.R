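test_that("PDB and mmCIF dialects parse to identical C-alpha records", {
  pdb <- writeTinyPDB(tempfile(fileext = ".pdb"))
  cif <- writeTinyCIF(tempfile(fileext = ".cif"))
  a <- readStructure(pdb)
  b <- readStructure(cif)
  expect_named(a, "A")
  expect_equal(nrow(a$A), 3L)
  expect_equal(a$A$seq, 1:3)
  expect_equal(a$A[c("seq", "x", "y", "z")], b$A[c("seq", "x", "y", "z")],
               tolerance = 1e-9)
  # explicit dialect selection also works
  expect_equal(readStructure(cif, format = "mmcif")$A$x, a$A$x)
})

test_that("HETATM-only input raises an empty-structure error", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A 101       1.000   2.000   3.000  1.00  0.00           O",
    "END"), f)
  expect_error(readStructure(f), class = "emptyStructureError")
  expect_error(readStructure("/no/such/file.pdb"), class = "ioError")
})

test_that("alternate locations resolve to the highest occupancy, first on tie", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.70  0.00           C",
    "ATOM      3  CA AALA A   2       3.800   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   2       8.800   0.000   0.000  0.50  0.00           C",
    "END"), f)
  ch <- readStructure(f)
  expect_equal(nrow(ch$A), 2L)
  expect_equal(ch$A$x, c(9.0, 3.8))  # highest occupancy; first wins the tie
})

test_that("extractDomain honours inclusive multi-segment CATH ranges", {
  coords <- cbind(seq(0, by = 3.8, length.out = 50), 0, 0)
  dom <- domainFromCoords(coords, "tstA01")
  pdb <- tempfile(fileext = ".pdb")
  writeMinimalPDB(dom, pdb)
  chains <- readStructure(pdb)

  one <- extractDomain(chains, "tstA01",
                       data.frame(chain = "A", start = 10, end = 20))
  expect_s4_class(one, "DomainStructure")
  expect_equal(nResidues(one), 11L)

  two <- extractDomain(chains, "tstA01",
                       data.frame(chain = "A", start = c(1, 40),
                                  end = c(5, 45)))
  expect_equal(nResidues(two), 11L)
  expect_equal(two@resSeq, c(1:5, 40:45))  # range order preserved

  expect_error(
    extractDomain(chains, "tstB01",
                  data.frame(chain = "B", start = 1, end = 10)),
    class = "emptyDomainError")
})

test_that("minimal-PDB round trip preserves numbering and coordinates", {
  xyz <- makeIdealHelix(8) + 11.113
  dom <- domainFromCoords(xyz, "rndA01")
  pdb <- tempfile(fileext = ".pdb")
  writeMinimalPDB(dom, pdb)
  back <- extractDomain(readStructure(pdb), "rndA01",
                        data.frame(chain = "A", start = 1, end = 8))
  expect_equal(back@resSeq, dom@resSeq)
  expect_lt(max(abs(caCoords(back) - caCoords(dom))), 1e-3)
  # extracting the full span is idempotent
  again <- extractDomain(readStructure(pdb), "rndA01",
                         data.frame(chain = "A", start = 1, end = 8))
  expect_equal(caCoords(again), caCoords(back))
})

test_that("chain segmentation flags breaks larger than the cutoff", {
  xyz <- rbind(cbind(seq(0, by = 3.8, length.out = 5), 0, 0),
               cbind(seq(40, by = 3.8, length.out = 5), 0, 0))
  dom <- domainFromCoords(xyz, "brkA01")
  seg <- chainSegments(dom)
  expect_equal(seg, rep(1:2, each = 5))
})

test_that("DomainStructure validity enforces the id format and uniqueness", {
  expect_error(DomainStructure("xxx", "yy", "A", 1L, "", cbind(1, 2, 3)),
               "sourceId")
  expect_error(
    DomainStructure("sssA01", "sss", c("A", "A"), c(1L, 1L), c("", ""),
                    rbind(c(0, 0, 0), c(3.8, 0, 0))),
    "duplicate")
})
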