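# Independent oracles used across the suite.

# elementwise formula addition on named integer vectors (deliberately a
# separate implementation from the package's formula helpers)
addF <- function(f, g) {
  els <- union(names(f), names(g))
  out <- setNames(integer(length(els)), els)
  out[names(f)] <- out[names(f)] + f
  out[names(g)] <- out[names(g)] + g
  out[out != 0L]
}

scaleF <- function(f, k) { out <- f * k; out[out != 0L] }

sameF <- function(f, g) {
  d <- addF(f, scaleF(g, -1L))
  length(d) == 0L
}

WATER <- c(H = 2L, O = 1L)

# formula removed when the given displaced-atom specs fire against a
# residue structure: an H spec removes one hydrogen from its heavy atom;
# a heavy spec removes that atom together with whatever implicit
# hydrogens it still carries after the H displacements (so "O1, H1"
# removes one O and one H in total, the hydroxyl of a carboxyl group)
displacedF <- function(specs, g) {
  out <- integer(0)
  hleft <- g@atoms$hcount
  for (s in specs) {
    if (s$element == "H") {
      out <- addF(out, c(H = 1L))
      hleft[s$index] <- hleft[s$index] - 1L
      stopifnot(hleft[s$index] >= 0L)
    }
  }
  for (s in specs) {
    if (s$element != "H") {
      out <- addF(out, setNames(1L, s$element))
      if (hleft[s$index] > 0L) out <- addF(out, c(H = hleft[s$index]))
    }
  }
  out
}

# Arithmetic formula of a polymer: sum of residue formulas minus the
# displaced atoms of every formed backbone bond and crosslink. This is
# pure formula bookkeeping -- no molecular graph is ever edited -- so it
# is an independent check on graph assembly.
oracleFormula <- function(p, ontology = builtinOntology()) {
  n <- length(p)
  f <- integer(0)
  for (occ in p@occurrences)
    f <- addF(f, getFormula(occ$residue@structure))
  pairs <- list()
  if (n > 1L)
    for (i in setdiff(seq_len(n - 1L), p@nicks)) pairs[[length(pairs) + 1L]] <- c(i, i + 1L)
  if (p@circular && !(n %in% p@nicks) && n > 1L)
    pairs[[length(pairs) + 1L]] <- c(n, 1L)
  for (pr in pairs) {
    ri <- p@occurrences[[pr[1]]]$residue
    rj <- p@occurrences[[pr[2]]]$residue
    f <- addF(f, scaleF(displacedF(ri@rDisplacedAtoms, ri@structure), -1L))
    f <- addF(f, scaleF(displacedF(rj@lDisplacedAtoms, rj@structure), -1L))
  }
  for (xl in p@crosslinks) {
    if (!is.na(xl$type)) {
      ty <- getCrosslinkType(ontology, xl$type)
      gl <- p@occurrences[[xl$l]]$residue@structure
      gr <- p@occurrences[[xl$r]]$residue@structure
      f <- addF(f, scaleF(displacedF(ty@lDisplacedAtoms, gl), -1L))
      f <- addF(f, scaleF(displacedF(ty@rDisplacedAtoms, gr), -1L))
    } else {
      for (e in c(xl$lDisplacedAtoms, xl$rDisplacedAtoms)) {
        g <- p@occurrences[[e$pos]]$residue@structure
        f <- addF(f, scaleF(displacedF(list(e$spec), g), -1L))
      }
    }
  }
  f
}

# random syntactically valid SMILES: chains of safely multivalent units,
# optional terminal decorations and dot components
randomSmiles <- function() {
  units <- c("C", "CC", "N", "S", "C(C)", "C(=O)", "C(N)", "C=C",
    "C1CCC1", "c1ccccc1", "C(F)(F)")
  k <- sample(1:5, 1)
  body <- paste(sample(units, k, replace = TRUE), collapse = "")
  if (runif(1) < 0.4)
    body <- paste0(body, sample(c("O", "Cl", "Br", "[O-]", "[NH3+]"), 1))
  if (runif(1) < 0.25)
    body <- paste0(body, ".", sample(c("[Na+]", "O", "[Cl-]", "CC"), 1))
  body
}

figureDimer <- function() {
  pep <- parsePolymer("AC{SEC}", "protein")
  cx <- parseComplex(
    "2 * pep | x-link: [type: disulfide | l: pep(1)-2 | r: pep(2)-2]",
    subunits = list(pep = pep))
  list(pep = pep, cx = cx)
}
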