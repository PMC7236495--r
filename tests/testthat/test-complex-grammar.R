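# Complex grammar: subunit stoichiometries and inter-subunit crosslinks.

test_that("the crosslinked homodimer and plain subunit bags parse", {
  d <- figureDimer()
  expect_length(d$cx@subunits, 1L)
  expect_equal(d$cx@subunits[[1]]$stoichiometry, 2L)
  expect_length(d$cx@crosslinks, 1L)
  xl <- d$cx@crosslinks[[1]]
  expect_identical(xl$type, "disulfide")
  expect_identical(xl$l$copy, 1L)
  expect_identical(xl$r$copy, 2L)
  expect_identical(xl$l$pos, 2L)

  cx2 <- parseComplex("1 * a + 2 * b")
  expect_equal(vapply(cx2@subunits, `[[`, 0L, "stoichiometry"), c(1L, 2L))
  expect_length(cx2@crosslinks, 0L)
})

test_that("parse rejects bad coordinates and malformed terms", {
  pep <- parsePolymer("AC{SEC}", "protein")
  expect_error(parseComplex(
    "2 * pep | x-link: [type: disulfide | l: pep(3)-2 | r: pep(1)-2]",
    subunits = list(pep = pep)), "copy index 3 exceeds stoichiometry 2")
  expect_error(parseComplex(
    "2 * pep | x-link: [type: disulfide | l: other(1)-2 | r: pep(1)-2]",
    subunits = list(pep = pep)), "unknown subunit")
  expect_error(parseComplex("pep"), "malformed subunit term")
  expect_error(parseComplex("2 * pep + 1 * pep"), "duplicate subunit")
  expect_error(parseComplex(
    "2 * pep | x-link: [type: disulfide | l: pep(1)-2 | r: pep(1)-2]"),
    "same residue")
  expect_warning(parseComplex("1 * solo"), "degenerate")
})

test_that("serialization round-trips, including explicit atom references", {
  pep <- parsePolymer("ACCG", "protein")
  texts <- c(
    "2 * pep | x-link: [type: disulfide | l: pep(1)-2 | r: pep(2)-2]",
    "2 * pep + 1 * other",
    "2 * pep | x-link: [l-bond-atom: pep(1)-2S7 | l-displaced-atom: pep(1)-2H7 | r-bond-atom: pep(2)-3S7 | r-displaced-atom: pep(2)-3H7]")
  for (tx in texts) {
    cx <- suppressWarnings(parseComplex(tx, subunits = list(pep = pep)))
    s <- serializeForm(cx)
    cx2 <- suppressWarnings(parseComplex(s, subunits = list(pep = pep)))
    expect_identical(serializeForm(cx2), s, info = tx)
  }
})

test_that("round trip is the identity on a seeded complex corpus", {
  recs <- generateComplexCorpus(40, seed = 21)
  for (rec in recs) {
    cx <- parseComplex(rec$text, subunits = rec$subunits)
    s <- serializeForm(cx)
    expect_identical(serializeForm(parseComplex(s, subunits = rec$subunits)),
      s, info = rec$text)
  }
})

test_that("an uncrosslinked n-mer has n times the subunit formula", {
  pep <- parsePolymer("GASP", "protein")
  f1 <- getFormula(pep)
  for (n in c(2L, 3L)) {
    cx <- parseComplex(sprintf("%d * pep", n), subunits = list(pep = pep))
    expect_true(sameF(getFormula(cx), scaleF(f1, n)), info = n)
  }
})
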