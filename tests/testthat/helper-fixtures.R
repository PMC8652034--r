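# Shared fixture builders. Heavy objects are memoized so several test files
# can reuse them without regenerating.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, builder) {
  v <- .fixtureCache[[key]]
  if (is.null(v)) {
    v <- builder()
    .fixtureCache[[key]] <- v
  }
  v
}

domainFromCoords <- function(coords, id = "synA01") {
  n <- nrow(coords)
  DomainStructure(id, substr(id, 1, nchar(id) - 3), rep("A", n), seq_len(n),
                  rep("", n), coords)
}

# the standard perturbed alpha/beta family used across annotation/layout
# tests: 10 members, 0.3 A coordinate jitter, fixed seed
jitteredFamily <- function() memoFixture("jfam", function() {
  fam <- makeFamily(familySpec(mixedRecipe(), nMembers = 10,
                               jitterSigma = 0.3, seed = 1))
  af <- annotateStructures(fam$familyId,
                           lapply(fam$members, `[[`, "structure"))
  list(raw = fam, annotated = af,
       stats = computeFamilyStats(af),
       truth = lapply(fam$members, `[[`, "truth"))
})

jitteredDiagrams <- function() memoFixture("jdiag", function()
  layoutFamily(jitteredFamily()$annotated, jitteredFamily()$stats))

# minimal hand-written structure files (canonical PDBx column order for the
# mmCIF dialect, which is what wwPDB emits)
writeTinyPDB <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  1.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  1.00           C",
    "ATOM      3  CA  ALA A   3       7.600   0.000   0.000  1.00  1.00           C",
    "END"), path)
  path
}

writeTinyCIF <- function(path) {
  writeLines(c(
    "data_tiny", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    "ATOM 1 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 1.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . ALA A 1 2 ? 3.800 0.000 0.000 1.00 1.00 ? 2 ALA A CA 1",
    "ATOM 3 C CA . ALA A 1 3 ? 7.600 0.000 0.000 1.00 1.00 ? 3 ALA A CA 1"),
    path)
  path
}

expect_sse_ranges_match <- function(detected, truth, tol = 2L) {
  expect_equal(nrow(detected), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    expect_identical(detected$type[i], truth$type[i])
    expect_lte(abs(detected$startIdx[i] - truth$startIdx[i]), tol)
    expect_lte(abs(detected$endIdx[i] - truth$endIdx[i]), tol)
  }
}
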