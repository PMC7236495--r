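# Semantic validation rules V1-V9 for polymers and complexes.

ruleSet <- function(report) unique(vErrors(report)$rule)

test_that("well-formed molecules validate cleanly", {
  expect_true(isClean(validatePolymer(parsePolymer("AC{SEC}", "protein"))))
  expect_true(isClean(validatePolymer(parsePolymer("{ACE}AC", "protein"))))
  expect_true(isClean(validatePolymer(parsePolymer("{m7G}AUG", "rna"))))
  expect_true(isClean(validatePolymer(parsePolymer("ACGT | circular", "dna"))))
  d <- figureDimer()
  expect_true(isClean(validateComplex(d$cx)))
})

test_that("misplaced caps violate cap placement (V2) and bondability (V1)", {
  rep <- validatePolymer(parsePolymer("A{ACE}G", "protein"))
  expect_true(all(c("V1", "V2") %in% ruleSet(rep)))
  # caps are fine exactly at chain ends created by nicks
  rep2 <- validatePolymer(parsePolymer("AC:{ACE}AG", "protein"))
  expect_true(isClean(rep2))
  # a circular polymer admits no caps at all
  rep3 <- validatePolymer(parsePolymer("{ACE}AG | circular", "protein"))
  expect_true(all(c("V2", "V3") %in% ruleSet(rep3)))
})

test_that("crosslink rules: out-of-range V6, allowed residues V7, double-use V8", {
  rep <- validatePolymer(parsePolymer(
    "ACD | x-link: [type: disulfide | l: 2 | r: 9]", "protein"))
  expect_identical(ruleSet(rep), "V6")
  expect_match(vErrors(rep)$message, "beyond the sequence length")

  rep2 <- validatePolymer(parsePolymer(
    "AC{SEC} | x-link: [type: disulfide | l: 1 | r: 2]", "protein"))
  expect_true("V7" %in% ruleSet(rep2))

  rep3 <- validatePolymer(parsePolymer(
    "CCCC | x-link: [type: disulfide | l: 1 | r: 2] | x-link: [type: disulfide | l: 1 | r: 3]",
    "protein"))
  expect_true("V8" %in% ruleSet(rep3))
})

test_that("atom references must resolve (V4) with hydrogens available (V5)", {
  rep <- validatePolymer(parsePolymer(
    "CC | x-link: [l-bond-atom: 1S2 | r-bond-atom: 2S7]", "protein"))
  expect_true("V4" %in% ruleSet(rep))
  expect_match(vErrors(rep)$message[1], "element mismatch")

  rep2 <- validatePolymer(parsePolymer(
    "CC | x-link: [l-bond-atom: 1S7 | r-bond-atom: 2S7 | l-displaced-atom: 1H2]",
    "protein"))
  expect_true("V5" %in% ruleSet(rep2))

  # inline residue whose own bond atoms do not fit its structure
  rep3 <- validatePolymer(parsePolymer(
    "A[id: bad | structure: \"NCC(O)=O\" | l-bond-atom: S1 | r-bond-atom: C3]G",
    "protein"))
  expect_true("V4" %in% ruleSet(rep3))
})

test_that("uncertainty ranges outside the sequence violate V9", {
  tx <- paste0("A[id: gx | structure: \"OC(=O)CN\" | l-bond-atom: N5",
    " | l-displaced-atom: H5 | r-bond-atom: C2 | r-displaced-atom: O1",
    " | r-displaced-atom: H1 | position: 2-9]G")
  rep <- validatePolymer(parsePolymer(tx, "protein"))
  expect_identical(ruleSet(rep), "V9")
})

test_that("a crosslink spanning a nick is flagged as a warning, not an error", {
  p <- suppressWarnings(parsePolymer(
    "CAC:AC | x-link: [type: disulfide | l: 1 | r: 5]", "protein"))
  rep <- validatePolymer(p)
  expect_true(isClean(rep))
  expect_true("W1" %in% vWarnings(rep)$rule)
})

test_that("complex validation checks coordinates, copies, and structures", {
  pep <- parsePolymer("AC{SEC}", "protein")
  cx <- complexForm(list(pep = list(stoichiometry = 2L, structure = pep)),
    crosslinks = list(list(type = "disulfide",
      l = list(subunit = "pep", copy = 3L, pos = 2L),
      r = list(subunit = "pep", copy = 1L, pos = 2L))))
  expect_true("V6" %in% ruleSet(validateComplex(cx)))

  cx2 <- complexForm(list(pep = list(stoichiometry = 2L, structure = pep)),
    crosslinks = list(list(type = "disulfide",
      l = list(subunit = "ghost", copy = 1L, pos = 2L),
      r = list(subunit = "pep", copy = 1L, pos = 2L))))
  expect_true("V6" %in% ruleSet(validateComplex(cx2)))

  cx3 <- complexForm(list(pep = list(stoichiometry = 2L, structure = NULL)))
  expect_false(isClean(validateComplex(cx3)))

  # a defective subunit propagates its findings with a prefixed location
  bad <- parsePolymer("A{ACE}G", "protein")
  cx4 <- complexForm(list(s = list(stoichiometry = 1L, structure = bad)))
  rep <- validateComplex(cx4)
  expect_true(all(c("V1", "V2") %in% ruleSet(rep)))
  expect_match(vErrors(rep)$location[1], "subunit s")
})

test_that("validation reports render as text and JSON", {
  rep <- validatePolymer(parsePolymer("A{ACE}G", "protein"))
  expect_match(formatReport(rep), "V2")
  js <- jsonlite::fromJSON(formatReport(rep, "json"))
  expect_false(js$clean)
  expect_true("V2" %in% js$errors$rule)
  expect_identical(formatReport(validatePolymer(parsePolymer("ACD", "protein"))),
    "clean")
})
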