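# SMILES subset parser/writer and molecular-graph property calculations.

test_that("parsing fills implicit hydrogens by the default-valence rule", {
  g <- parseSmiles("NCC(O)=O")  # glycine
  expect_equal(g@atoms$element, c("N", "C", "C", "O", "O"))
  expect_equal(g@atoms$hcount, c(2L, 2L, 0L, 1L, 0L))
  expect_equal(g@atoms$charge, rep(0L, 5))
  expect_equal(nrow(g@bonds), 4L)

  h <- parseSmiles("[H]")
  expect_equal(h@atoms$element, "H")
  expect_equal(h@atoms$hcount, 0L)
  expect_equal(h@atoms$charge, 0L)

  ring <- parseSmiles("C1CC1")
  expect_equal(ring@atoms$element, rep("C", 3))
  expect_equal(ring@atoms$hcount, rep(2L, 3))
  expect_equal(nrow(ring@bonds), 3L)
  expect_setequal(paste(ring@bonds$a, ring@bonds$b),
    c("1 2", "2 3", "1 3"))
  expect_true(all(ring@bonds$order == "single"))
})

test_that("parse errors carry a character offset and the failing construct", {
  expect_error(parseSmiles("C(C"), "unbalanced parentheses")
  expect_error(parseSmiles("CC)C"), "character 3.*unbalanced parentheses")
  expect_error(parseSmiles("C1CC"), "dangling ring closure")
  expect_error(parseSmiles("[Xx]"), "unknown element")
  expect_error(parseSmiles("O(C)(C)C"), "valence overflow")
  expect_error(parseSmiles("C/C=C/C"), "stereochemistry")
  expect_error(parseSmiles("C[C@H](N)O"), "stereochemistry")
  expect_error(parseSmiles(""), "empty")
  expect_warning(parseSmiles("[13C]"), "isotope")
})

test_that("aromatic input is kekulized; impossible systems are rejected", {
  benzene <- parseSmiles("c1ccccc1")
  expect_equal(sum(benzene@bonds$order == "double"), 3L)
  expect_equal(sum(benzene@bonds$order == "single"), 3L)
  expect_equal(benzene@atoms$hcount, rep(1L, 6))
  pyridine <- parseSmiles("c1ccncc1")
  expect_equal(pyridine@atoms$hcount[pyridine@atoms$element == "N"], 0L)
  # an odd count of unsaturated aromatic atoms admits no alternation
  expect_error(parseSmiles("c1ccccc1c"), "kekulize")
  expect_silent(parseSmiles("c1cc[nH]c1"))  # pyrrole
  imidazole <- parseSmiles("c1cnc[nH]1")
  expect_equal(sum(imidazole@bonds$order == "double"), 2L)
})

test_that("written SMILES re-parses to an isomorphic graph", {
  cases <- c("NCC(O)=O", "C1CC1", "c1ccccc1", "C%12CC%12",
    "OC(=O)C(N)Cc1c[nH]c2ccccc12", "O.O.[Na+]",
    "OP(=O)(O)OCC1OC(CC1O)n2cnc3c(N)ncnc23")
  for (s in cases) {
    g <- parseSmiles(s)
    g2 <- parseSmiles(writeSmiles(g))
    expect_true(graphIsomorphic(g, g2), info = s)
  }
  # determinism
  g <- parseSmiles("OC(=O)C(N)CS")
  expect_identical(writeSmiles(g), writeSmiles(g))
})

test_that("round trip holds on a seeded corpus of random SMILES", {
  set.seed(4242)
  for (i in 1:120) {
    s <- randomSmiles()
    g <- parseSmiles(s)
    g2 <- parseSmiles(writeSmiles(g))
    expect_true(graphIsomorphic(g, g2), info = s)
  }
})

test_that("charged and non-organic atoms are written in brackets", {
  o <- molecularGraph(
    data.frame(element = "O", charge = -1L, hcount = 0L))
  expect_identical(writeSmiles(o), "[O-]")
  se <- parseSmiles("[SeH2]")
  expect_identical(writeSmiles(se), "[SeH2]")
  expect_error(writeSmiles(molecularGraph()), "empty")
})

test_that("formula, weight, and charge follow the element counts", {
  gly <- parseSmiles("NCC(O)=O")
  expect_identical(formulaString(getFormula(gly)), "C2H5NO2")
  expect_identical(formulaString(getFormula(parseSmiles("O"))), "H2O")
  expect_identical(formulaString(getFormula(parseSmiles("[Na+]"))), "Na")
  expect_equal(getMolWeight(gly), 75.07, tolerance = 0.01)
  expect_equal(getMolWeight(parseSmiles("O")), 18.02, tolerance = 0.01)
  expect_error(getMolWeight(molecularGraph()), "empty")
  expect_identical(getCharge(gly), 0L)
  expect_identical(getCharge(parseSmiles("[NH4+]")), 1L)
  expect_identical(getCharge(parseSmiles("[O-]P([O-])(=O)O")), -2L)
})

test_that("formulas add over dot-disconnected components and weights are linear", {
  set.seed(99)
  for (i in 1:25) {
    a <- randomSmiles(); b <- randomSmiles()
    fa <- getFormula(parseSmiles(a))
    fb <- getFormula(parseSmiles(b))
    fab <- getFormula(parseSmiles(paste(a, b, sep = ".")))
    expect_true(sameF(fab, addF(fa, fb)), info = paste(a, b))
    w <- elementWeights()
    g <- parseSmiles(a)
    f <- getFormula(g)
    expect_equal(getMolWeight(g), sum(w[names(f)] * f), info = a)
  }
})

test_that("atomAt guards element identity at an index", {
  gly <- parseSmiles("NCC(O)=O")
  expect_equal(atomAt(gly, "N", 1)$index, 1L)
  expect_equal(atomAt(gly, "O", 4)$hcount, 1L)  # the hydroxyl oxygen
  expect_error(atomAt(gly, "S", 1), "expected S, found N")
  expect_error(atomAt(gly, "C", 9), "out of range")
})
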