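# Equality and structured diff.

test_that("a polymer equals its serialize-parse image; diffs localize edits", {
  p <- parsePolymer("AC{pS}D | circular", "protein")
  q <- parsePolymer(serializeForm(p), "protein")
  expect_true(molEqual(p, q))
  expect_equal(nrow(molDiff(p, q)), 0L)

  a <- parsePolymer("AC{SEC}", "protein")
  b <- parsePolymer("ACC", "protein")
  d <- molDiff(a, b)
  expect_false(molEqual(a, b))
  expect_true(any(d$kind == "sequence" & d$location == "position 3"))
})

test_that("inline residues normalize to their alphabet equivalents", {
  inline <- parsePolymer(paste0(
    "A[id: gx | structure: \"OC(=O)CN\" | l-bond-atom: N5 | l-displaced-atom: H5",
    " | r-bond-atom: C2 | r-displaced-atom: O1 | r-displaced-atom: H1",
    " | base-monomer: G]G"), "protein")
  plain <- parsePolymer("AGG", "protein")
  expect_true(molEqual(inline, plain))
  # a genuinely novel structure does not collapse onto the alphabet
  novel <- parsePolymer(paste0(
    "A[id: nx | structure: \"OC(=O)C(N)CCS\" | l-bond-atom: N5",
    " | l-displaced-atom: H5 | r-bond-atom: C2 | r-displaced-atom: O1",
    " | r-displaced-atom: H1]G"), "protein")
  expect_false(molEqual(novel, plain))
})

test_that("attribute changes surface in the diff", {
  a <- parsePolymer("ACDG", "protein")
  b <- parsePolymer("ACDG | circular", "protein")
  c_ <- parsePolymer("ACDG | extra: [mass: 10 | charge: 1]", "protein")
  expect_true(any(molDiff(a, b)$location == "circular"))
  expect_true(any(molDiff(a, c_)$kind == "attribute"))
  n1 <- parsePolymer("AC:DG", "protein")
  expect_true(any(molDiff(a, n1)$kind == "nicks"))
  x1 <- parsePolymer("CCDG | x-link: [type: disulfide | l: 1 | r: 2]", "protein")
  x0 <- parsePolymer("CCDG", "protein")
  expect_true(any(molDiff(x0, x1)$kind == "crosslink"))
})

test_that("equality behaves as an equivalence relation on a seeded corpus", {
  corp <- generateCorpus(corpusSpec(40, seed = 17, pModified = 0.3,
    pNick = 0.3, pCrosslink = 0.3))
  ps <- lapply(corp$text, parsePolymer, alphabet = "protein")
  for (i in seq_along(ps)) {
    expect_true(molEqual(ps[[i]], ps[[i]]))                 # reflexive
    j <- sample(seq_along(ps), 1)
    expect_identical(molEqual(ps[[i]], ps[[j]]), molEqual(ps[[j]], ps[[i]]))
    expect_identical(molEqual(ps[[i]], ps[[j]]),
      nrow(molDiff(ps[[i]], ps[[j]])) == 0L)                # diff consistency
  }
})

test_that("complex equality holds up to permutation of interchangeable copies", {
  pep <- parsePolymer("AC{SEC}", "protein")
  a <- parseComplex("2 * pep | x-link: [type: disulfide | l: pep(1)-2 | r: pep(2)-2]",
    subunits = list(pep = pep))
  b <- parseComplex("2 * pep | x-link: [type: disulfide | l: pep(2)-2 | r: pep(1)-2]",
    subunits = list(pep = pep))
  expect_true(molEqual(a, b))
  expect_equal(nrow(molDiff(a, b)), 0L)

  other <- parsePolymer("ACCG", "protein")
  c1 <- parseComplex("2 * pep + 1 * q", subunits = list(pep = pep, q = other))
  c2 <- parseComplex("2 * pep + 1 * q", subunits = list(pep = pep, q = pep))
  expect_false(molEqual(c1, c2))
  c3 <- parseComplex("3 * pep", subunits = list(pep = pep))
  c4 <- parseComplex("2 * pep", subunits = list(pep = pep))
  expect_false(molEqual(c3, c4))
})

test_that("three-copy crosslink patterns compare up to relabeling", {
  pep <- parsePolymer("ACCG", "protein")
  mk <- function(i, j) parseComplex(sprintf(
    "3 * pep | x-link: [type: disulfide | l: pep(%d)-2 | r: pep(%d)-3]", i, j),
    subunits = list(pep = pep))
  expect_true(molEqual(mk(1, 2), mk(2, 3)))
  expect_true(molEqual(mk(1, 3), mk(3, 1)))
  # a self-copy link is not equivalent to a cross-copy link
  self1 <- parseComplex(
    "3 * pep | x-link: [type: disulfide | l: pep(1)-2 | r: pep(1)-3]",
    subunits = list(pep = pep))
  expect_false(molEqual(self1, mk(1, 2)))
})
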