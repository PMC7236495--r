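# Assembly into molecular graphs and the derived properties.

test_that("peptide-bond formation loses exactly one water per bond", {
  gg <- parsePolymer("GG", "protein")
  expect_identical(formulaString(getFormula(gg)), "C4H8N2O3")
  g1 <- getFormula(parsePolymer("G", "protein"))
  expect_true(sameF(getFormula(gg),
    addF(scaleF(g1, 2L), scaleF(WATER, -1L))))
  # chain-length law at a few n
  for (n in c(1L, 2L, 5L, 10L)) {
    p <- parsePolymer(strrep("G", n), "protein")
    expect_equal(getMolWeight(p), n * 75.067 - (n - 1) * 18.015,
      tolerance = 0.01 * n, info = n)
  }
})

test_that("a circular trimer closes the ring and loses three waters", {
  p <- parsePolymer("GGG | circular", "protein")
  g <- assemble(p)
  expect_identical(formulaString(getFormula(g)), "C6H9N3O3")
  # three backbone bonds on top of the residues' own bonds after the
  # displaced hydroxyls are deleted
  internal <- sum(vapply(p@occurrences, function(o)
    nrow(o$residue@structure@bonds) - length(o$residue@rDisplacedAtoms[
      vapply(o$residue@rDisplacedAtoms, function(s) s$element != "H", TRUE)]),
    0L))
  expect_equal(nrow(g@bonds), internal + 3L)
})

test_that("the crosslinked selenopeptide dimer matches residue arithmetic", {
  d <- figureDimer()
  # arithmetic oracle: 2 x (sum of the three residues - 2 waters) - 2 H
  resF <- lapply(c("A", "C", "U"), function(code)
    getFormula(getResidue(builtinAlphabet("protein"), code)@structure))
  trip <- addF(addF(resF[[1]], resF[[2]]), resF[[3]])
  trip <- addF(trip, scaleF(WATER, -2L))
  dimer_expect <- addF(scaleF(trip, 2L), c(H = -2L))
  expect_true(sameF(getFormula(d$cx), dimer_expect))
  expect_identical(formulaString(getFormula(d$cx)), "C18H32N6O8S2Se2")
  expect_equal(getMolWeight(d$cx), 682.54, tolerance = 0.01)
  expect_identical(getCharge(d$cx), 0L)
})

test_that("assembled formulas equal the arithmetic oracle on a seeded corpus", {
  corp <- generateCorpus(corpusSpec(120, seed = 31, pModified = 0.3,
    pNick = 0.3, pCrosslink = 0.3, pCircular = 0.2))
  for (tx in corp$text) {
    p <- parsePolymer(tx, "protein")
    expect_true(sameF(getFormula(p), oracleFormula(p)), info = tx)
  }
  corp2 <- generateCorpus(corpusSpec(40, "dna", seed = 32))
  for (tx in corp2$text) {
    p <- parsePolymer(tx, "dna")
    expect_true(sameF(getFormula(p), oracleFormula(p)), info = tx)
  }
})

test_that("a nicked polymer equals the complex of its fragments", {
  set.seed(77)
  al <- builtinAlphabet("protein")
  canonical <- strsplit("GAVLIPFWMSTCYNQDEKRH", "")[[1]]
  for (i in 1:10) {
    L <- sample(4:10, 1)
    codes <- sample(canonical, L, replace = TRUE)
    cut <- sample(seq_len(L - 1L), 1)
    nicked <- polymer(codes, al, nicks = cut)
    frag1 <- polymer(codes[1:cut], al)
    frag2 <- polymer(codes[(cut + 1):L], al)
    cx <- complexForm(list(a = frag1, b = frag2))
    expect_true(sameF(getFormula(nicked), getFormula(cx)))
    expect_equal(getMolWeight(nicked), getMolWeight(cx), tolerance = 1e-9)
    expect_identical(getCharge(nicked), getCharge(cx))
  }
})

test_that("extra observed mass and charge reach weight and charge, not the formula", {
  p <- parsePolymer("AG | extra: [mass: 79.97 | charge: -2]", "protein")
  p0 <- parsePolymer("AG", "protein")
  expect_true(sameF(getFormula(p), getFormula(p0)))
  expect_equal(getMolWeight(p), getMolWeight(p0) + 79.97, tolerance = 1e-9)
  expect_identical(getCharge(p), getCharge(p0) - 2L)
})

test_that("assembly on invalid input reports the validation failure", {
  expect_error(assemble(parsePolymer("A{ACE}G", "protein")),
    "fails validation")
})

test_that("SMILES export reflects connectivity: nicks split, crosslinks join", {
  g <- parsePolymer("G", "protein")
  expect_identical(formulaString(getFormula(parseSmiles(exportSmiles(g)))),
    "C2H5NO2")
  nicked <- parsePolymer("GG:GG", "protein")
  expect_length(strsplit(exportSmiles(nicked), ".", fixed = TRUE)[[1]], 2L)
  d <- figureDimer()
  expect_length(strsplit(exportSmiles(d$cx), ".", fixed = TRUE)[[1]], 1L)
  # the exported string re-parses to the assembled graph
  expect_true(graphIsomorphic(parseSmiles(exportSmiles(d$cx)),
    assemble(d$cx)))
})

test_that("charge deltas of atom specs are applied when bonds form", {
  tx <- paste0(
    "[id: x1 | structure: \"NCC(O)=O\" | r-bond-atom: C3+1 | r-displaced-atom: O4 | r-displaced-atom: H4]",
    "[id: x2 | structure: \"NCC(O)=O\" | l-bond-atom: N1-1 | l-displaced-atom: H1]")
  p <- parsePolymer(tx, "protein")
  g <- assemble(p)
  expect_identical(getCharge(g), 0L)
  expect_setequal(g@atoms$charge[g@atoms$charge != 0L], c(1L, -1L))
})
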