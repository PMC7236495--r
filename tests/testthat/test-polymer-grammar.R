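# Polymer grammar: parsing, serialization, round trips.

test_that("codes, brace codes, circularity, and nicks parse as described", {
  p <- parsePolymer("AC{SEC}", "protein")
  expect_equal(length(p), 3L)
  expect_identical(vapply(p@occurrences, function(o) o$residue@id, ""),
    c("ala", "cys", "sec"))

  p2 <- parsePolymer("ACGT | circular", "dna")
  expect_equal(length(p2), 4L)
  expect_true(p2@circular)

  p3 <- parsePolymer("AA:GG", "protein")
  expect_equal(length(p3), 4L)
  expect_identical(p3@nicks, 2L)

  expect_error(parsePolymer("AC{SEC} | x-link: [type: disulfide | l: 2 | r: 2]",
    "protein"), "same residue")
})

test_that("syntax errors are located and list expected tokens", {
  err <- tryCatch(parsePolymer("AC(Q", "protein"), error = identity)
  expect_s3_class(err, "mf_syntax_error")
  expect_match(conditionMessage(err), "line 1, column 3")
  expect_match(conditionMessage(err), "expected residue code")
  expect_error(parsePolymer("", "protein"), "empty")
  expect_error(parsePolymer("A{", "protein"), "unclosed")
  expect_error(parsePolymer(":A", "protein"), "nick cannot precede")
  expect_error(parsePolymer("A | wat", "protein"), "unknown attribute")
  expect_error(parsePolymer("AB", "protein"), "unknown residue code")
  expect_error(parsePolymer("A | x-link: [type: staple | l: 1 | r: 2]",
    "protein"), "unknown crosslink")
})

test_that("serialization round-trips structurally, attributes in fixed order", {
  texts <- c(
    "AC{SEC}",
    "ACGT | circular",
    "AA:GG",
    "AC{pS}D | x-link: [type: disulfide | l: 2 | r: 4] | extra: [mass: 79.97 | charge: -2]",
    "CC | x-link: [l-bond-atom: 1S7 | l-displaced-atom: 1H7 | r-bond-atom: 2S7 | r-displaced-atom: 2H7]",
    "A[id: gx | structure: \"OC(=O)CN\" | l-bond-atom: N5 | l-displaced-atom: H5 | r-bond-atom: C2 | r-displaced-atom: O1 | r-displaced-atom: H1 | base-monomer: G | position: 1-2]G")
  al <- if (TRUE) "protein"
  for (tx in texts) {
    alph <- if (grepl("ACGT", tx)) "dna" else "protein"
    p <- parsePolymer(tx, alph)
    s <- serializeForm(p)
    p2 <- parsePolymer(s, alph)
    expect_identical(serializeForm(p2), s, info = tx)
    expect_true(molEqual(p, p2), info = tx)
  }
})

test_that("inline residues keep their SMILES verbatim through serialization", {
  tx <- "A[id: gx | structure: \"NCC(O)=O\" | l-bond-atom: N1 | r-bond-atom: C3]G"
  p <- parsePolymer(tx, "protein")
  expect_match(serializeForm(p), "NCC(O)=O", fixed = TRUE)
  # extra mass and charge survive the round trip
  p2 <- parsePolymer("AG | extra: [mass: 79.97 | charge: -2]", "protein")
  p3 <- parsePolymer(serializeForm(p2), "protein")
  expect_equal(p3@extraMass, 79.97)
  expect_identical(p3@extraCharge, -2L)
})

test_that("round trip is the identity on a large seeded corpus", {
  corp <- generateCorpus(corpusSpec(400, seed = 7, pModified = 0.3,
    pNick = 0.3, pCrosslink = 0.3, pCircular = 0.2))
  for (tx in corp$text) {
    p <- parsePolymer(tx, "protein")
    s <- serializeForm(p)
    expect_identical(serializeForm(parsePolymer(s, "protein")), s, info = tx)
  }
})

test_that("every record of the seeded syntax-error corpus is rejected with a located error", {
  corp <- generateCorpus(corpusSpec(60, seed = 13, errorMode = "syntax"))
  for (tx in corp$text) {
    err <- tryCatch({ parsePolymer(tx, "protein"); NULL }, error = identity)
    expect_false(is.null(err), info = tx)
    expect_s3_class(err, "mf_error")
  }
})

test_that("plain canonical strings parse and re-export unchanged", {
  al <- builtinAlphabet("protein")
  set.seed(5)
  canonical <- strsplit("GAVLIPFWMSTCYNQDEKRH", "")[[1]]
  for (i in 1:20) {
    s <- paste(sample(canonical, sample(3:20, 1), replace = TRUE),
      collapse = "")
    expect_identical(canonicalSequence(parsePolymer(s, al)), s, info = s)
  }
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:30, 1), replace = TRUE),
      collapse = "")
    expect_identical(canonicalSequence(parsePolymer(s, "dna")), s, info = s)
  }
})

test_that("residueAt bounds-checks its position", {
  p <- parsePolymer("AC{SEC}", "protein")
  expect_identical(residueAt(p, 3)$residue@id, "sec")
  expect_error(residueAt(p, 4), "out of range")
  expect_error(residueAt(p, 0), "out of range")
})
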