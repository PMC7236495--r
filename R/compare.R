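# Equality and structured diff of described molecules. Equality is
# defined on normalized canonical serializations: inline residues are
# matched to alphabet residues by structure isomorphism, crosslinks are
# canonically ordered, and complexes are compared up to permutation of
# the interchangeable copies of each subunit.

specStrings <- function(specs) vapply(specs, formatAtomSpec, "")

sameSpecs <- function(a, b) identical(specStrings(a), specStrings(b))

# replace an inline residue by the alphabet residue it is isomorphic to
# (same structure graph and identical bond/displaced atom references), if
# any; returns the occurrence unchanged otherwise
normalizeOccurrence <- function(occ, alphabet) {
  if (!occ$inline) return(occ)
  r <- occ$residue
  for (cand in alphabet@residues) {
    if (numAtoms(cand@structure) != numAtoms(r@structure)) next
    if (!sameSpecs(cand@lBondAtoms, r@lBondAtoms)) next
    if (!sameSpecs(cand@rBondAtoms, r@rBondAtoms)) next
    if (!sameSpecs(cand@lDisplacedAtoms, r@lDisplacedAtoms)) next
    if (!sameSpecs(cand@rDisplacedAtoms, r@rDisplacedAtoms)) next
    if (!graphIsomorphic(cand@structure, r@structure)) next
    occ$residue <- cand
    occ$code <- cand@code
    occ$inline <- FALSE
    occ$smiles <- NULL
    return(occ)
  }
  occ
}

normalizePolymer <- function(p) {
  p@occurrences <- lapply(p@occurrences, normalizeOccurrence,
    alphabet = p@alphabet)
  # aliases resolve to the registry code
  p@occurrences <- lapply(p@occurrences, function(occ) {
    if (!occ$inline && !identical(occ$code, occ$residue@code))
      occ$code <- occ$residue@code
    occ
  })
  if (length(p@crosslinks) > 1L) {
    keys <- vapply(p@crosslinks, serializeCrosslink, "")
    p@crosslinks <- p@crosslinks[order(keys)]
  }
  p
}

#' Canonical serialization of a polymer
#'
#' [serializeForm()] after normalization; two polymers are [molEqual()]
#' exactly when their canonical serializations are identical.
#'
#' @param p a [Polymer-class]
#' @return single character string
#' @export
canonicalSerialization <- function(p) serializeForm(normalizePolymer(p))

#' @describeIn molEqual polymer equality on normalized canonical
#'   serializations
#' @export
setMethod("molEqual", signature("Polymer", "Polymer"), function(a, b, ...) {
  identical(canonicalSerialization(a), canonicalSerialization(b))
})

occToken <- function(p, i) {
  occ <- p@occurrences[[i]]
  if (occ$inline) serializeInline(occ)
  else if (nchar(occ$code) == 1L) occ$code
  else paste0("{", occ$code, "}")
}

#' @describeIn molDiff positionwise polymer diff
#' @export
setMethod("molDiff", signature("Polymer", "Polymer"), function(a, b, ...) {
  na <- normalizePolymer(a); nb <- normalizePolymer(b)
  rows <- list()
  add <- function(kind, location, va, vb, message)
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, location = location,
      a = va, b = vb, message = message, stringsAsFactors = FALSE)
  la <- length(na); lb <- length(nb)
  if (la != lb)
    add("length", "sequence", as.character(la), as.character(lb),
      sprintf("sequence lengths differ (%d vs %d)", la, lb))
  for (i in seq_len(min(la, lb))) {
    ta <- occToken(na, i); tb <- occToken(nb, i)
    ra <- na@occurrences[[i]]$range; rb <- nb@occurrences[[i]]$range
    if (!identical(ta, tb) || !identical(ra, rb))
      add("sequence", sprintf("position %d", i), ta, tb,
        sprintf("residues differ at position %d", i))
  }
  if (!identical(na@nicks, nb@nicks))
    add("nicks", "sequence", paste(na@nicks, collapse = ","),
      paste(nb@nicks, collapse = ","), "nick positions differ")
  xa <- vapply(na@crosslinks, serializeCrosslink, "")
  xb <- vapply(nb@crosslinks, serializeCrosslink, "")
  for (x in setdiff(xa, xb)) add("crosslink", "crosslinks", x, "", "crosslink only in a")
  for (x in setdiff(xb, xa)) add("crosslink", "crosslinks", "", x, "crosslink only in b")
  if (!identical(na@circular, nb@circular))
    add("attribute", "circular", as.character(na@circular),
      as.character(nb@circular), "circularity differs")
  if (!identical(na@extraMass, nb@extraMass))
    add("attribute", "extra mass", as.character(na@extraMass),
      as.character(nb@extraMass), "extra observed mass differs")
  if (!identical(na@extraCharge, nb@extraCharge))
    add("attribute", "extra charge", as.character(na@extraCharge),
      as.character(nb@extraCharge), "extra observed charge differs")
  if (!identical(na@comments, nb@comments))
    add("attribute", "comments", paste(na@comments, collapse = " "),
      paste(nb@comments, collapse = " "), "comments differ")
  if (length(rows) == 0L &&
      !identical(serializeForm(na), serializeForm(nb)))
    add("attribute", "serialization", serializeForm(na), serializeForm(nb),
      "serializations differ")
  if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), location = character(), a = character(),
      b = character(), message = character(), stringsAsFactors = FALSE)
})

permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# canonical crosslink multiset of a complex: lexicographically minimal
# sorted serialization over all copy permutations of the subunits that
# appear in crosslinks (copies are interchangeable except as
# distinguished by crosslinks)
canonicalComplexCrosslinks <- function(x) {
  if (length(x@crosslinks) == 0L) return(character())
  ids <- vapply(x@subunits, `[[`, "", "id")
  stoich <- stats::setNames(vapply(x@subunits, `[[`, 0L, "stoichiometry"), ids)
  slotsOf <- function(xl) {
    if (!is.na(xl$type)) list(xl$l, xl$r) else
      lapply(c(xl$lBondAtoms, xl$rBondAtoms, xl$lDisplacedAtoms,
        xl$rDisplacedAtoms), function(e) e[c("subunit", "copy", "pos")])
  }
  touched <- unique(unlist(lapply(x@crosslinks, function(xl)
    vapply(slotsOf(xl), `[[`, "", "subunit"))))
  touched <- intersect(touched, ids)
  if (any(stoich[touched] > 8L))
    stop("copy-permutation search capped at stoichiometry 8 (got ",
      max(stoich[touched]), ")")
  permsPer <- lapply(touched, function(id) permutations(seq_len(stoich[[id]])))
  names(permsPer) <- touched
  applyPerm <- function(assignment) {
    relabel <- function(s) {
      if (s$subunit %in% touched) s$copy <- assignment[[s$subunit]][s$copy]
      s
    }
    keys <- vapply(x@crosslinks, function(xl) {
      xl2 <- xl
      if (!is.na(xl2$type)) {
        xl2$l <- relabel(xl2$l); xl2$r <- relabel(xl2$r)
      } else {
        for (fld in c("lBondAtoms", "rBondAtoms", "lDisplacedAtoms",
            "rDisplacedAtoms"))
          xl2[[fld]] <- lapply(xl2[[fld]], function(e) {
            e[c("subunit", "copy")] <- relabel(e)[c("subunit", "copy")]; e })
      }
      fmtSlot <- function(s) sprintf("%s(%d)-%d", s$subunit, s$copy, s$pos)
      if (!is.na(xl2$type))
        sprintf("type:%s|l:%s|r:%s", xl2$type, fmtSlot(xl2$l), fmtSlot(xl2$r))
      else {
        fmtRef <- function(e) paste0(fmtSlot(e), formatAtomSpec(e$spec))
        paste0("explicit|",
          paste(vapply(xl2$lBondAtoms, fmtRef, ""), collapse = ","), "|",
          paste(vapply(xl2$rBondAtoms, fmtRef, ""), collapse = ","), "|",
          paste(vapply(xl2$lDisplacedAtoms, fmtRef, ""), collapse = ","), "|",
          paste(vapply(xl2$rDisplacedAtoms, fmtRef, ""), collapse = ","))
      }
    }, "")
    sort(keys)
  }
  best <- NULL
  recurse <- function(i, assignment) {
    if (i > length(touched)) {
      keys <- applyPerm(assignment)
      key1 <- paste(keys, collapse = ";")
      if (is.null(best) || key1 < paste(best, collapse = ";")) best <<- keys
      return(invisible())
    }
    for (perm in permsPer[[i]]) {
      assignment[[touched[i]]] <- perm
      recurse(i + 1L, assignment)
    }
  }
  recurse(1L, list())
  best
}

#' @describeIn molEqual complex equality: subunits matched by id
#'   (stoichiometry and structure), crosslinks up to permutation of the
#'   interchangeable copies of each subunit (exhaustive search, capped at
#'   stoichiometry 8)
#' @export
setMethod("molEqual", signature("ComplexForm", "ComplexForm"),
  function(a, b, ...) {
    nrow(molDiff(a, b)) == 0L
  })

#' @describeIn molDiff complex diff: per-subunit stoichiometry/structure
#'   discrepancies plus the crosslink comparison after canonical copy
#'   relabeling
#' @export
setMethod("molDiff", signature("ComplexForm", "ComplexForm"),
  function(a, b, ...) {
    rows <- list()
    add <- function(kind, location, va, vb, message)
      rows[[length(rows) + 1L]] <<- data.frame(kind = kind,
        location = location, a = va, b = vb, message = message,
        stringsAsFactors = FALSE)
    idsA <- vapply(a@subunits, `[[`, "", "id")
    idsB <- vapply(b@subunits, `[[`, "", "id")
    for (id in setdiff(idsA, idsB))
      add("subunit", id, "present", "absent", "subunit only in a")
    for (id in setdiff(idsB, idsA))
      add("subunit", id, "absent", "present", "subunit only in b")
    for (id in intersect(idsA, idsB)) {
      sa <- a@subunits[[match(id, idsA)]]
      sb <- b@subunits[[match(id, idsB)]]
      if (sa$stoichiometry != sb$stoichiometry)
        add("subunit", id, as.character(sa$stoichiometry),
          as.character(sb$stoichiometry), "stoichiometries differ")
      same <- if (is.null(sa$structure) && is.null(sb$structure)) TRUE
        else if (is(sa$structure, "Polymer") && is(sb$structure, "Polymer"))
          molEqual(sa$structure, sb$structure)
        else if (is(sa$structure, "MolecularGraph") &&
            is(sb$structure, "MolecularGraph"))
          graphIsomorphic(sa$structure, sb$structure)
        else FALSE
      if (!same)
        add("subunit", id, "structure", "structure",
          "subunit structures differ")
    }
    xa <- canonicalComplexCrosslinks(a)
    xb <- canonicalComplexCrosslinks(b)
    if (!identical(xa, xb)) {
      for (x in setdiff(xa, xb))
        add("crosslink", "crosslinks", x, "", "crosslink only in a")
      for (x in setdiff(xb, xa))
        add("crosslink", "crosslinks", "", x, "crosslink only in b")
      if (length(setdiff(xa, xb)) == 0L && length(setdiff(xb, xa)) == 0L)
        add("crosslink", "crosslinks", paste(xa, collapse = ";"),
          paste(xb, collapse = ";"), "crosslink multiplicities differ")
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(kind = character(), location = character(), a = character(),
        b = character(), message = character(), stringsAsFactors = FALSE)
  })
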