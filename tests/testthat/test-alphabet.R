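# Alphabet and crosslink-ontology data model and YAML I/O.

test_that("the packaged protein alphabet carries the curated residue set", {
  al <- builtinAlphabet("protein")
  canonical <- strsplit("GAVLIPFWMSTCYNQDEKRH", "")[[1]]
  expect_true(all(canonical %in% names(al@residues)))
  expect_true(all(c("U", "pS", "pT", "pY", "HYP", "ACE") %in%
    names(al@residues)))
  ace <- getResidue(al, "ACE")
  expect_length(ace@lBondAtoms, 0L)   # left cap
  expect_gt(length(ace@rBondAtoms), 0L)
  # every spec resolves against its structure with the right element
  for (r in al@residues) {
    for (spec in c(r@lBondAtoms, r@rBondAtoms, r@lDisplacedAtoms,
        r@rDisplacedAtoms)) {
      if (spec$element == "H") {
        expect_gte(r@structure@atoms$hcount[spec$index], 1L)
      } else {
        expect_identical(r@structure@atoms$element[spec$index], spec$element,
          info = r@code)
      }
    }
  }
})

test_that("the RNA fixture carries a 5' cap with no left bond atoms", {
  rna <- builtinAlphabet("rna")
  cap <- getResidue(rna, "m7G")
  expect_length(cap@lBondAtoms, 0L)
  expect_length(cap@baseMonomers, 0L)
  expect_identical(getCharge(cap@structure), 1L)  # N7-methyl cation
  expect_true(all(c("A", "C", "G", "U", "PSI") %in% names(rna@residues)))
})

test_that("save followed by load reproduces each fixture alphabet", {
  for (type in c("protein", "dna", "rna")) {
    al <- builtinAlphabet(type)
    path <- tempfile(fileext = ".yml")
    saveAlphabet(al, path)
    al2 <- loadAlphabet(path)
    expect_identical(names(al2@residues), names(al@residues))
    for (code in names(al@residues)) {
      r1 <- al@residues[[code]]; r2 <- al2@residues[[code]]
      expect_true(graphIsomorphic(r1@structure, r2@structure), info = code)
      for (sl in c("lBondAtoms", "rBondAtoms", "lDisplacedAtoms",
          "rDisplacedAtoms"))
        expect_identical(
          vapply(slot(r2, sl), formatAtomSpec, ""),
          vapply(slot(r1, sl), formatAtomSpec, ""), info = paste(code, sl))
      expect_identical(r2@baseMonomers, r1@baseMonomers)
      expect_identical(r2@aliases, r1@aliases)
    }
    unlink(path)
  }
})

test_that("loading rejects unresolvable atom references, naming the residue", {
  path <- tempfile(fileext = ".yml")
  writeLines(c(
    "id: broken", "type: protein", "residues:",
    "- code: 'Z'", "  structure: NCC(O)=O", "  l_bond_atoms: [S1]"), path)
  expect_error(loadAlphabet(path), "residue Z.*S1")
  unlink(path)
})

test_that("duplicate residue codes and crosslink ids are load errors", {
  path <- tempfile(fileext = ".yml")
  writeLines(c(
    "id: dup", "type: protein", "residues:",
    "- code: 'A'", "  structure: C",
    "- code: 'A'", "  structure: O"), path)
  expect_error(loadAlphabet(path), "duplicate")
  writeLines(c(
    "crosslinks:",
    "- id: disulfide", "  l_bond_atoms: [S7]", "  r_bond_atoms: [S7]",
    "- id: disulfide", "  l_bond_atoms: [S7]", "  r_bond_atoms: [S7]"), path)
  expect_error(loadOntology(path), "duplicate")
  unlink(path)
})

test_that("residue lookup resolves aliases and suggests near misses", {
  al <- builtinAlphabet("protein")
  expect_identical(getResidue(al, "A")@id, "ala")
  expect_identical(getResidue(al, "SEC")@id, "sec")   # alias
  expect_identical(getResidue(al, "U")@id, "sec")     # registry code
  err <- tryCatch(getResidue(al, "!"), error = identity)
  expect_s3_class(err, "mf_unknown_code")
  expect_match(conditionMessage(err), "nearest codes")
})

test_that("the seed ontology encodes disulfide chemistry on cysteine sulfurs", {
  ont <- builtinOntology()
  expect_true(all(c("disulfide", "isopeptide_K_G", "thioester") %in%
    names(ont@types)))
  ds <- getCrosslinkType(ont, "disulfide")
  cys <- getResidue(builtinAlphabet("protein"), "C")@structure
  expect_identical(ds@lBondAtoms[[1]]$element, "S")
  expect_identical(ds@rBondAtoms[[1]]$element, "S")
  expect_identical(ds@lDisplacedAtoms[[1]]$element, "H")
  expect_identical(ds@rDisplacedAtoms[[1]]$element, "H")
  # the S index points at the thiol sulfur, which bears the displaceable H
  expect_identical(cys@atoms$element[ds@lBondAtoms[[1]]$index], "S")
  expect_gte(cys@atoms$hcount[ds@lDisplacedAtoms[[1]]$index], 1L)
  expect_error(getCrosslinkType(ont, "nope"), "unknown crosslink")
})

test_that("atom specs round-trip through their compact text form", {
  for (s in c("C2", "H1", "O3-1", "N7+2", "Se12")) {
    expect_identical(formatAtomSpec(parseAtomSpec(s)), s)
  }
  expect_error(parseAtomSpec("X"), "malformed")
  expect_error(parseAtomSpec("2C"), "malformed")
})
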