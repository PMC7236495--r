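# Complex grammar: subunit stoichiometries plus inter-subunit crosslinks.
#
#   complex := term { "+" term } { "|" attr }
#   term    := INT "*" ID
#   attr    := "x-link: [" xfield { "|" xfield } "]"
#   slot    := ID "(" copy ")" "-" residue_pos          (type-based l:/r:)
#   atomref := ID "(" copy ")" "-" pos element idx [+n|-n]   (explicit)
#
# Subunit structures (polymers or small-molecule graphs) are supplied
# out-of-band through the `subunits` mapping; copies of a subunit are
# interchangeable except as distinguished by crosslinks.

parseSubunitSlot <- function(value, text, pos) {
  m <- regmatches(value, regexec(
    "^([A-Za-z][A-Za-z0-9_.-]*)\\(([0-9]+)\\)-([0-9]+)$", value))[[1]]
  if (length(m) == 0L)
    syntaxError(text, pos, paste0("malformed subunit slot '", value,
      "' (expected id(copy)-residue, e.g. pep(1)-2)"))
  list(subunit = m[2], copy = as.integer(m[3]), pos = as.integer(m[4]))
}

parseSubunitAtomRef <- function(value, text, pos) {
  m <- regmatches(value, regexec(
    "^([A-Za-z][A-Za-z0-9_.-]*)\\(([0-9]+)\\)-([0-9]+)([A-Z][a-z]?)([0-9]+)([+-][0-9]+)?$",
    value))[[1]]
  if (length(m) == 0L)
    syntaxError(text, pos, paste0("malformed subunit atom reference '", value,
      "' (expected id(copy)-<residue><element><atom>, e.g. pep(1)-2S7)"))
  list(subunit = m[2], copy = as.integer(m[3]), pos = as.integer(m[4]),
    spec = atomSpec(m[5], as.integer(m[6]),
      if (nzchar(m[7])) as.integer(m[7]) else 0L))
}

slotKey <- function(s) paste(s$subunit, s$copy, s$pos, sep = "/")

#' Parse a complex description
#'
#' Parses the complex grammar: `+`-separated subunit terms
#' (`stoichiometry * id`) followed by `|`-separated crosslink attributes
#' whose slots address residues hierarchically as `id(copy)-position`.
#' Subunit structures are attached from the `subunits` mapping when
#' provided; semantic validation requires them.
#'
#' @param text complex description (single string)
#' @param subunits named list mapping subunit id to a [Polymer-class] or a
#'   [MolecularGraph-class] (small-molecule subunit); may be empty
#' @param ontology a [CrosslinkOntology-class]
#' @return a [ComplexForm-class]
#' @examples
#' pep <- parsePolymer("AC{SEC}", "protein")
#' cx <- parseComplex("2 * pep | x-link: [type: disulfide | l: pep(1)-2 | r: pep(2)-2]",
#'   subunits = list(pep = pep))
#' @export
parseComplex <- function(text, subunits = list(),
    ontology = builtinOntology()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop(errorCondition("empty complex description",
      class = c("mf_syntax_error", "mf_error")))
  sp <- splitTop(text)
  terms <- splitTop(sp$pieces[1], sep = "+")
  subs <- list()
  for (i in seq_along(terms$pieces)) {
    term <- trimws(terms$pieces[i])
    m <- regmatches(term, regexec(
      "^([0-9]+)\\s*\\*\\s*([A-Za-z][A-Za-z0-9_.-]*)$", term))[[1]]
    if (length(m) == 0L)
      syntaxError(text, terms$starts[i],
        paste0("malformed subunit term '", term, "'"),
        "stoichiometry * id (e.g. 2 * pep)")
    id <- m[3]
    st <- as.integer(m[2])
    if (st < 1L)
      syntaxError(text, terms$starts[i], "stoichiometry must be >= 1")
    subs[[length(subs) + 1L]] <- list(id = id, stoichiometry = st,
      structure = subunits[[id]])
  }
  ids <- vapply(subs, `[[`, "", "id")
  if (anyDuplicated(ids))
    syntaxError(text, 1L, paste0("duplicate subunit id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  stoich <- stats::setNames(vapply(subs, `[[`, 0L, "stoichiometry"), ids)
  crosslinks <- list()
  if (length(sp$pieces) > 1L) {
    for (k in 2:length(sp$pieces)) {
      piece <- trimws(sp$pieces[k])
      ppos <- sp$starts[k]
      f <- parseField(piece)
      if (is.null(f) || f$name != "x-link")
        syntaxError(text, ppos, paste0("unknown attribute '", piece, "'"),
          "x-link:")
      if (!grepl("^\\[.*\\]$", f$value))
        syntaxError(text, ppos, "x-link attribute must be enclosed in [ ]")
      body <- substr(f$value, 2L, nchar(f$value) - 1L)
      fs <- splitTop(body)
      xl <- list(type = NA_character_, l = NULL, r = NULL,
        lBondAtoms = list(), rBondAtoms = list(),
        lDisplacedAtoms = list(), rDisplacedAtoms = list())
      for (i in seq_along(fs$pieces)) {
        fp <- fs$pieces[i]
        if (!nzchar(trimws(fp))) next
        g <- parseField(fp)
        fpos <- ppos + fs$starts[i]
        if (is.null(g))
          syntaxError(text, fpos, paste0("malformed x-link field '",
            trimws(fp), "'"),
            c("type:", "l:", "r:", "l-bond-atom:", "r-bond-atom:",
              "l-displaced-atom:", "r-displaced-atom:"))
        val <- g$value
        switch(g$name,
          "type" = {
            if (!is.null(ontology)) getCrosslinkType(ontology, val)
            xl$type <- val
          },
          "l" = { xl$l <- parseSubunitSlot(val, text, fpos) },
          "r" = { xl$r <- parseSubunitSlot(val, text, fpos) },
          "l-bond-atom" = { xl$lBondAtoms <- c(xl$lBondAtoms,
            list(parseSubunitAtomRef(val, text, fpos))) },
          "r-bond-atom" = { xl$rBondAtoms <- c(xl$rBondAtoms,
            list(parseSubunitAtomRef(val, text, fpos))) },
          "l-displaced-atom" = { xl$lDisplacedAtoms <- c(xl$lDisplacedAtoms,
            list(parseSubunitAtomRef(val, text, fpos))) },
          "r-displaced-atom" = { xl$rDisplacedAtoms <- c(xl$rDisplacedAtoms,
            list(parseSubunitAtomRef(val, text, fpos))) },
          syntaxError(text, fpos, paste0("unknown x-link field '",
            g$name, "'"))
        )
      }
      if (!is.na(xl$type)) {
        if (is.null(xl$l) || is.null(xl$r))
          syntaxError(text, ppos, "type-based x-link needs both l: and r: slots")
      } else {
        if (length(xl$lBondAtoms) == 0L || length(xl$rBondAtoms) == 0L)
          syntaxError(text, ppos,
            "x-link must carry a type or explicit l-/r-bond-atom references")
        xl$l <- xl$lBondAtoms[[1]][c("subunit", "copy", "pos")]
        xl$r <- xl$rBondAtoms[[1]][c("subunit", "copy", "pos")]
      }
      # parse-time coordinate checks against the stoichiometries in the text
      for (side in c("l", "r")) {
        s <- xl[[side]]
        if (!s$subunit %in% ids)
          syntaxError(text, ppos, paste0("x-link references unknown subunit '",
            s$subunit, "'"))
        if (s$copy > stoich[[s$subunit]])
          syntaxError(text, ppos, sprintf(
            "x-link copy index %d exceeds stoichiometry %d of subunit '%s'",
            s$copy, stoich[[s$subunit]], s$subunit))
      }
      if (identical(slotKey(xl$l), slotKey(xl$r)))
        syntaxError(text, ppos,
          "x-link endpoints refer to the same residue of the same subunit copy")
      crosslinks[[length(crosslinks) + 1L]] <- xl
    }
  }
  if (length(subs) == 1L && subs[[1]]$stoichiometry == 1L &&
      length(crosslinks) == 0L)
    warning("degenerate complex: a single subunit with stoichiometry 1 and no crosslinks",
      call. = FALSE)
  new("ComplexForm", subunits = subs, crosslinks = crosslinks)
}

#' @describeIn serializeForm serialize a complex; subunits in input order
#'   with stoichiometry coefficients, then crosslinks
#' @export
setMethod("serializeForm", "ComplexForm", function(x, ...) {
  terms <- vapply(x@subunits, function(s)
    sprintf("%d * %s", s$stoichiometry, s$id), "")
  out <- paste(terms, collapse = " + ")
  fmtSlot <- function(s) sprintf("%s(%d)-%d", s$subunit, s$copy, s$pos)
  attrs <- vapply(x@crosslinks, function(xl) {
    if (!is.na(xl$type)) {
      sprintf("x-link: [type: %s | l: %s | r: %s]", xl$type,
        fmtSlot(xl$l), fmtSlot(xl$r))
    } else {
      fmtRef <- function(e) paste0(
        sprintf("%s(%d)-%d", e$subunit, e$copy, e$pos), formatAtomSpec(e$spec))
      parts <- c(
        vapply(xl$lBondAtoms, function(e) paste0("l-bond-atom: ", fmtRef(e)), ""),
        vapply(xl$lDisplacedAtoms, function(e)
          paste0("l-displaced-atom: ", fmtRef(e)), ""),
        vapply(xl$rBondAtoms, function(e) paste0("r-bond-atom: ", fmtRef(e)), ""),
        vapply(xl$rDisplacedAtoms, function(e)
          paste0("r-displaced-atom: ", fmtRef(e)), ""))
      paste0("x-link: [", paste(parts, collapse = " | "), "]")
    }
  }, "")
  if (length(attrs)) out <- paste(c(out, attrs), collapse = " | ")
  out
})

#' Construct a complex programmatically
#'
#' @param subunits named list mapping subunit id to
#'   `list(stoichiometry =, structure =)` or simply to a structure (then
#'   stoichiometry 1)
#' @param crosslinks list of crosslinks in the [ComplexForm-class] shape
#' @return a [ComplexForm-class]
#' @export
complexForm <- function(subunits, crosslinks = list()) {
  subs <- lapply(names(subunits), function(id) {
    s <- subunits[[id]]
    if (is(s, "Polymer") || is(s, "MolecularGraph"))
      s <- list(stoichiometry = 1L, structure = s)
    list(id = id, stoichiometry = as.integer(s$stoichiometry),
      structure = s$structure)
  })
  crosslinks <- lapply(crosslinks, function(xl) {
    base <- list(type = NA_character_, l = NULL, r = NULL,
      lBondAtoms = list(), rBondAtoms = list(),
      lDisplacedAtoms = list(), rDisplacedAtoms = list())
    base[names(xl)] <- xl
    base
  })
  new("ComplexForm", subunits = subs, crosslinks = crosslinks)
}

#' Attach subunit structures to a parsed complex
#'
#' @param x a [ComplexForm-class]
#' @param subunits named list mapping subunit id to structure
#' @return the complex with structures attached
#' @export
attachSubunits <- function(x, subunits) {
  stopifnot(is(x, "ComplexForm"))
  x@subunits <- lapply(x@subunits, function(s) {
    if (!is.null(subunits[[s$id]])) s$structure <- subunits[[s$id]]
    s
  })
  x
}

setMethod("show", "ComplexForm", function(object) {
  cat(sprintf("Complex: %d subunit type(s), %d crosslink(s)\n  %s\n",
    length(object@subunits), length(object@crosslinks),
    serializeForm(object)))
})
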