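# Canonical sequences, FASTA export, reference QC.

test_that("canonical sequences map residues to their base monomers", {
  expect_identical(canonicalSequence(parsePolymer("AC{SEC}", "protein")), "ACU")
  expect_identical(canonicalSequence(parsePolymer("A{pS}D", "protein")), "ASD")
  expect_identical(canonicalSequence(parsePolymer("{HYP}G", "protein")), "PG")
  # a cap with no recorded parent maps to the unknown code
  expect_identical(canonicalSequence(parsePolymer("{m7G}AUG", "rna")), "NAUG")
  expect_identical(canonicalSequence(parsePolymer("{ACE}AG", "protein")), "XAG")
  expect_identical(canonicalSequence(parsePolymer("{m6A}CGT", "dna")), "ACGT")
})

test_that("FASTA export writes 80-column records readable by standard parsers", {
  long <- parsePolymer(strrep("ACDEFGHIKL", 12), "protein")   # 120 residues
  short <- parsePolymer("AC{SEC}", "protein")
  path <- tempfile(fileext = ".fasta")
  exportFasta(list(tripeptide = short, big = long), path)
  set <- Biostrings::readBStringSet(path)
  expect_identical(names(set), c("tripeptide", "big"))
  expect_identical(as.character(set[["tripeptide"]]), "ACU")
  expect_identical(as.character(set[["big"]]), strrep("ACDEFGHIKL", 12))
  raw <- readLines(path)
  expect_true(all(nchar(raw) <= 80L))
  unlink(path)
})

test_that("reference QC flags structure/sequence inconsistencies", {
  # a phosphoserine annotated at the position of a tyrosine
  p <- parsePolymer("A{pS}D", "protein")
  rep <- checkAgainstReference(p, "AYD")
  expect_false(isClean(rep))
  expect_true(any(vErrors(rep)$rule == "Q2"))
  expect_match(vErrors(rep)$message[vErrors(rep)$rule == "Q2"], "derives from S")
  # exact canonical match is clean
  expect_true(isClean(checkAgainstReference(p, "ASD")))
  # length mismatch
  expect_true(any(vErrors(checkAgainstReference(p, "ASDF"))$rule == "Q1"))
})

test_that("an initiator-methionine offset reconciles coordinate systems", {
  # the reference still carries its initiator methionine; the polymer is
  # numbered from the processed protein
  p <- parsePolymer("A{pS}D", "protein")
  expect_false(isClean(checkAgainstReference(p, "MASD")))      # without offset
  expect_true(isClean(checkAgainstReference(p, "MASD", offset = 1)))
})

test_that("wildcard residues (no base monomers) warn instead of failing", {
  p <- parsePolymer("{ACE}AG", "protein")
  rep <- checkAgainstReference(p, "XAG")
  expect_true(isClean(rep))
  expect_true(any(vWarnings(rep)$rule == "Q3"))
})
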