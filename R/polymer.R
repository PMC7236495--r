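# Polymer grammar: sequences of residues (alphabet codes, brace codes, or
# inline definitions), nicks (":"), attributes for circularity, crosslinks,
# extra observed mass/charge, and comments.
#
#   polymer := seq { "|" attr }
#   seq     := { unit } ; unit := LETTER | "{" CODE "}" | "[" inline "]" | ":"
#   inline  := field { "|" field }   fields: id, structure ("SMILES"),
#              l-bond-atom, r-bond-atom, l-displaced-atom, r-displaced-atom
#              (repeatable, e.g. C2 / H1 / O3-1), base-monomer, position
#              (lo-hi), comments ("...")
#   attr    := "circular" | "x-link: [" xfield { "|" xfield } "]"
#            | "extra: [ mass: R | charge: Z ]" | 'comments: "..."'
#   xfield  := type: ID | l: INT | r: INT
#            | l-bond-atom: <pos><element><idx>[+n|-n] | ... (r-/displaced)
#
# Whitespace is insignificant outside quotes; the grammar is case-sensitive.

lineCol <- function(text, pos) {
  pre <- substr(text, 1L, max(0L, pos - 1L))
  nl <- gregexpr("\n", pre, fixed = TRUE)[[1]]
  if (nl[1] == -1L) c(1L, pos) else c(length(nl) + 1L, pos - nl[length(nl)])
}

syntaxError <- function(text, pos, msg, expected = NULL) {
  lc <- lineCol(text, pos)
  exp <- if (length(expected))
    paste0("; expected ", paste(expected, collapse = ", ")) else ""
  stop(errorCondition(
    sprintf("syntax error at line %d, column %d: %s%s", lc[1], lc[2], msg, exp),
    class = c("mf_syntax_error", "mf_error")))
}

# split a string on `sep` at top level (outside [..], {..}, and "..")
splitTop <- function(text, sep = "|") {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L; quoted <- FALSE
  pieces <- character(); starts <- integer()
  cur <- 1L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (quoted) { if (ch == "\"") quoted <- FALSE; next }
    if (ch == "\"") { quoted <- TRUE; next }
    if (ch %in% c("[", "{")) depth <- depth + 1L
    else if (ch %in% c("]", "}")) depth <- depth - 1L
    else if (ch == sep && depth == 0L) {
      pieces <- c(pieces, substr(text, cur, i - 1L))
      starts <- c(starts, cur)
      cur <- i + 1L
    }
  }
  if (quoted) syntaxError(text, nchar(text), "unterminated quoted string")
  pieces <- c(pieces, substr(text, cur, nchar(text)))
  starts <- c(starts, cur)
  list(pieces = pieces, starts = starts)
}

trimws1 <- function(x) trimws(x)

# parse 'name: value' (value may be empty for flag-like fields)
parseField <- function(piece) {
  m <- regmatches(piece, regexec("^\\s*([A-Za-z][A-Za-z0-9-]*)\\s*:(.*)$", piece))[[1]]
  if (length(m) == 0L) return(NULL)
  list(name = m[2], value = trimws(m[3]))
}

unquote <- function(value, text, pos) {
  if (!grepl('^".*"$', value))
    syntaxError(text, pos, paste0("expected a quoted string, got '", value, "'"))
  substr(value, 2L, nchar(value) - 1L)
}

# (pos, atom-spec) reference used in explicit crosslink fields, e.g. "2S7-1"
parsePosAtomRef <- function(value, text, pos) {
  m <- regmatches(value, regexec("^([0-9]+)([A-Z][a-z]?)([0-9]+)([+-][0-9]+)?$",
    value))[[1]]
  if (length(m) == 0L)
    syntaxError(text, pos, paste0("malformed atom reference '", value,
      "' (expected <residue><element><atom>[+n|-n], e.g. 2S7)"))
  list(pos = as.integer(m[2]),
    spec = atomSpec(m[3], as.integer(m[4]),
      if (nzchar(m[5])) as.integer(m[5]) else 0L))
}

parseInlineResidue <- function(body, alphabet, text, pos0) {
  sp <- splitTop(body)
  fields <- list(id = NULL, structure = NULL, comments = NULL, position = NULL)
  lb <- list(); rb <- list(); ld <- list(); rd <- list(); bm <- character()
  for (i in seq_along(sp$pieces)) {
    piece <- sp$pieces[i]
    if (!nzchar(trimws(piece))) next
    f <- parseField(piece)
    if (is.null(f))
      syntaxError(text, pos0 + sp$starts[i],
        paste0("malformed inline-residue field '", trimws(piece), "'"),
        c("id:", "structure:", "l-bond-atom:", "r-bond-atom:",
          "l-displaced-atom:", "r-displaced-atom:", "base-monomer:",
          "position:", "comments:"))
    val <- f$value
    fpos <- pos0 + sp$starts[i]
    switch(f$name,
      "id" = { fields$id <- val },
      "structure" = { fields$structure <- unquote(val, text, fpos) },
      "l-bond-atom" = { lb[[length(lb) + 1L]] <- parseAtomSpec(val) },
      "r-bond-atom" = { rb[[length(rb) + 1L]] <- parseAtomSpec(val) },
      "l-displaced-atom" = { ld[[length(ld) + 1L]] <- parseAtomSpec(val) },
      "r-displaced-atom" = { rd[[length(rd) + 1L]] <- parseAtomSpec(val) },
      "base-monomer" = { bm <- c(bm, val) },
      "position" = {
        m <- regmatches(val, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", val))[[1]]
        if (length(m) == 0L)
          syntaxError(text, fpos, paste0("malformed position range '", val, "'"))
        fields$position <- c(as.integer(m[2]), as.integer(m[3]))
      },
      "comments" = { fields$comments <- unquote(val, text, fpos) },
      syntaxError(text, fpos, paste0("unknown inline-residue field '",
        f$name, "'"))
    )
  }
  if (is.null(fields$structure))
    syntaxError(text, pos0, "inline residue must declare a structure")
  g <- tryCatch(parseSmiles(fields$structure), error = function(e)
    syntaxError(text, pos0, paste0("inline residue structure: ",
      conditionMessage(e))))
  id <- fields$id %||% "inline"
  r <- new("Residue", code = id, id = id, name = id, structure = g,
    lBondAtoms = lb, rBondAtoms = rb, lDisplacedAtoms = ld,
    rDisplacedAtoms = rd, baseMonomers = bm, aliases = character(),
    xrefs = list(),
    comments = fields$comments %||% character())
  list(residue = r, smiles = fields$structure, range = fields$position,
    comments = fields$comments)
}

parseCrosslinkAttr <- function(value, ontology, text, pos0, n) {
  if (!grepl("^\\[.*\\]$", value))
    syntaxError(text, pos0, "x-link attribute must be enclosed in [ ]")
  body <- substr(value, 2L, nchar(value) - 1L)
  sp <- splitTop(body)
  xl <- list(type = NA_character_, l = NA_integer_, r = NA_integer_,
    lBondAtoms = list(), rBondAtoms = list(),
    lDisplacedAtoms = list(), rDisplacedAtoms = list())
  for (i in seq_along(sp$pieces)) {
    piece <- sp$pieces[i]
    if (!nzchar(trimws(piece))) next
    f <- parseField(piece)
    fpos <- pos0 + sp$starts[i]
    if (is.null(f))
      syntaxError(text, fpos, paste0("malformed x-link field '",
        trimws(piece), "'"),
        c("type:", "l:", "r:", "l-bond-atom:", "r-bond-atom:",
          "l-displaced-atom:", "r-displaced-atom:"))
    val <- f$value
    switch(f$name,
      "type" = {
        if (!is.null(ontology)) getCrosslinkType(ontology, val)  # raises if unknown
        xl$type <- val
      },
      "l" = { xl$l <- suppressWarnings(as.integer(val)) },
      "r" = { xl$r <- suppressWarnings(as.integer(val)) },
      "l-bond-atom" = { xl$lBondAtoms <- c(xl$lBondAtoms,
        list(parsePosAtomRef(val, text, fpos))) },
      "r-bond-atom" = { xl$rBondAtoms <- c(xl$rBondAtoms,
        list(parsePosAtomRef(val, text, fpos))) },
      "l-displaced-atom" = { xl$lDisplacedAtoms <- c(xl$lDisplacedAtoms,
        list(parsePosAtomRef(val, text, fpos))) },
      "r-displaced-atom" = { xl$rDisplacedAtoms <- c(xl$rDisplacedAtoms,
        list(parsePosAtomRef(val, text, fpos))) },
      syntaxError(text, fpos, paste0("unknown x-link field '", f$name, "'"))
    )
  }
  if (!is.na(xl$type)) {
    if (is.na(xl$l) || is.na(xl$r))
      syntaxError(text, pos0, "type-based x-link needs both l: and r: positions")
    if (xl$l == xl$r)
      syntaxError(text, pos0,
        "x-link l and r refer to the same residue; a crosslink joins two distinct residues")
    xl$lBondAtoms <- list(); xl$rBondAtoms <- list()
    xl$lDisplacedAtoms <- list(); xl$rDisplacedAtoms <- list()
  } else {
    if (length(xl$lBondAtoms) == 0L || length(xl$rBondAtoms) == 0L)
      syntaxError(text, pos0,
        "x-link must carry a type or explicit l-/r-bond-atom references")
    xl$l <- xl$lBondAtoms[[1]]$pos; xl$r <- xl$rBondAtoms[[1]]$pos
    if (xl$l == xl$r && all(vapply(xl$rBondAtoms, `[[`, 0L, "pos") == xl$l))
      syntaxError(text, pos0, "x-link l and r refer to the same residue")
  }
  xl
}

#' Parse a polymer description
#'
#' Parses the polymer grammar (see the package vignette): residue codes of
#' the alphabet (single letters bare, longer codes in braces), inline
#' residue definitions in square brackets, nicks written `:` between
#' residues, and `|`-separated attributes for circularity, crosslinks,
#' extra observed mass/charge, and comments. Syntax errors report line and
#' column and the tokens expected.
#'
#' @param text polymer description (single string)
#' @param alphabet an [Alphabet-class], or one of `"protein"`, `"dna"`,
#'   `"rna"` to use the packaged fixture alphabets
#' @param ontology a [CrosslinkOntology-class] for resolving named
#'   crosslink types (default: the packaged ontology)
#' @return a [Polymer-class]
#' @examples
#' p <- parsePolymer("AC{SEC}", "protein")
#' length(p)
#' canonicalSequence(p)
#' @export
parsePolymer <- function(text, alphabet, ontology = builtinOntology()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop(errorCondition("empty polymer description",
      class = c("mf_syntax_error", "mf_error")))
  if (is.character(alphabet)) alphabet <- builtinAlphabet(alphabet)
  stopifnot(is(alphabet, "Alphabet"))
  sp <- splitTop(text)
  seqtext <- sp$pieces[1]
  occurrences <- list()
  nicks <- integer()
  chars <- strsplit(seqtext, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (grepl("^[A-Za-z]$", ch)) {
      r <- getResidue(alphabet, ch)
      occurrences[[length(occurrences) + 1L]] <- list(residue = r, code = ch,
        inline = FALSE, smiles = NULL, range = NULL, comments = NULL)
      i <- i + 1L; next
    }
    if (ch == "{") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= length(chars)) { if (chars[j] == "}") { close <- j; break }
        j <- j + 1L }
      if (is.na(close)) syntaxError(text, i, "unclosed '{'")
      code <- trimws(substr(seqtext, i + 1L, close - 1L))
      if (!nzchar(code)) syntaxError(text, i, "empty residue code in braces")
      r <- getResidue(alphabet, code)
      occurrences[[length(occurrences) + 1L]] <- list(residue = r, code = code,
        inline = FALSE, smiles = NULL, range = NULL, comments = NULL)
      i <- close + 1L; next
    }
    if (ch == "[") {
      depth <- 1L; quoted <- FALSE; close <- NA_integer_
      j <- i + 1L
      while (j <= length(chars)) {
        cj <- chars[j]
        if (quoted) { if (cj == "\"") quoted <- FALSE }
        else if (cj == "\"") quoted <- TRUE
        else if (cj == "[") depth <- depth + 1L
        else if (cj == "]") { depth <- depth - 1L
          if (depth == 0L) { close <- j; break } }
        j <- j + 1L
      }
      if (is.na(close)) syntaxError(text, i, "unclosed '['")
      inl <- parseInlineResidue(substr(seqtext, i + 1L, close - 1L),
        alphabet, text, i)
      occurrences[[length(occurrences) + 1L]] <- list(residue = inl$residue,
        code = inl$residue@code, inline = TRUE, smiles = inl$smiles,
        range = inl$range, comments = inl$comments)
      i <- close + 1L; next
    }
    if (ch == ":") {
      pos <- length(occurrences)
      if (pos == 0L)
        syntaxError(text, i, "a nick cannot precede the first residue")
      if (pos %in% nicks)
        syntaxError(text, i, "duplicate nick position")
      nicks <- c(nicks, pos)
      i <- i + 1L; next
    }
    syntaxError(text, i, paste0("unexpected character '", ch, "'"),
      c("residue code", "'{'", "'['", "':'", "'|'"))
  }
  n <- length(occurrences)
  if (n == 0L)
    syntaxError(text, 1L, "polymer contains no residues")
  circular <- FALSE
  crosslinks <- list()
  extraMass <- NA_real_; extraCharge <- NA_integer_
  comments <- character()
  if (length(sp$pieces) > 1L) {
    for (k in 2:length(sp$pieces)) {
      piece <- trimws(sp$pieces[k])
      ppos <- sp$starts[k]
      if (piece == "circular") { circular <- TRUE; next }
      f <- parseField(piece)
      if (is.null(f))
        syntaxError(text, ppos, paste0("unknown attribute '", piece, "'"),
          c("circular", "x-link:", "extra:", "comments:"))
      switch(f$name,
        "x-link" = {
          crosslinks[[length(crosslinks) + 1L]] <-
            parseCrosslinkAttr(f$value, ontology, text, ppos, n)
        },
        "extra" = {
          if (!grepl("^\\[.*\\]$", f$value))
            syntaxError(text, ppos, "extra attribute must be enclosed in [ ]")
          body <- substr(f$value, 2L, nchar(f$value) - 1L)
          for (part in splitTop(body)$pieces) {
            g <- parseField(part)
            if (is.null(g))
              syntaxError(text, ppos, paste0("malformed extra field '",
                trimws(part), "'"), c("mass:", "charge:"))
            if (g$name == "mass") extraMass <- as.numeric(g$value)
            else if (g$name == "charge") extraCharge <- as.integer(g$value)
            else syntaxError(text, ppos, paste0("unknown extra field '",
              g$name, "'"), c("mass:", "charge:"))
          }
        },
        "comments" = { comments <- unquote(f$value, text, ppos) },
        syntaxError(text, ppos, paste0("unknown attribute '", f$name, "'"),
          c("circular", "x-link:", "extra:", "comments:"))
      )
    }
  }
  p <- tryCatch(
    new("Polymer", alphabet = alphabet, occurrences = occurrences,
      nicks = sort(unique(nicks)), crosslinks = crosslinks,
      circular = circular, extraMass = extraMass, extraCharge = extraCharge,
      comments = comments),
    error = function(e) stop(errorCondition(
      paste0("invalid polymer: ", conditionMessage(e)),
      class = c("mf_syntax_error", "mf_error"))))
  if (length(p@nicks) && length(p@crosslinks)) {
    for (xl in p@crosslinks) {
      lo <- min(xl$l, xl$r); hi <- max(xl$l, xl$r)
      if (any(p@nicks >= lo & p@nicks < hi))
        warning("crosslink between residues ", xl$l, " and ", xl$r,
          " spans a nick", call. = FALSE)
    }
  }
  p
}

serializeInline <- function(occ) {
  r <- occ$residue
  fields <- character()
  if (!identical(r@id, "inline")) fields <- c(fields, paste0("id: ", r@id))
  smi <- occ$smiles %||% writeSmiles(r@structure)
  fields <- c(fields, paste0("structure: \"", smi, "\""))
  addSpecs <- function(name, specs) vapply(specs, function(s)
    paste0(name, ": ", formatAtomSpec(s)), "")
  fields <- c(fields,
    addSpecs("l-bond-atom", r@lBondAtoms),
    addSpecs("l-displaced-atom", r@lDisplacedAtoms),
    addSpecs("r-bond-atom", r@rBondAtoms),
    addSpecs("r-displaced-atom", r@rDisplacedAtoms),
    vapply(r@baseMonomers, function(b) paste0("base-monomer: ", b), ""))
  if (!is.null(occ$range))
    fields <- c(fields, sprintf("position: %d-%d", occ$range[1], occ$range[2]))
  if (length(occ$comments) && nzchar(occ$comments))
    fields <- c(fields, paste0("comments: \"", occ$comments, "\""))
  paste0("[", paste(fields, collapse = " | "), "]")
}

serializeCrosslink <- function(xl, slotFmt = function(pos) as.character(pos)) {
  if (!is.na(xl$type)) {
    sprintf("x-link: [type: %s | l: %s | r: %s]", xl$type,
      slotFmt(xl$l), slotFmt(xl$r))
  } else {
    parts <- c(
      vapply(xl$lBondAtoms, function(e) paste0("l-bond-atom: ",
        slotFmt(e$pos), formatAtomSpec(e$spec)), ""),
      vapply(xl$lDisplacedAtoms, function(e) paste0("l-displaced-atom: ",
        slotFmt(e$pos), formatAtomSpec(e$spec)), ""),
      vapply(xl$rBondAtoms, function(e) paste0("r-bond-atom: ",
        slotFmt(e$pos), formatAtomSpec(e$spec)), ""),
      vapply(xl$rDisplacedAtoms, function(e) paste0("r-displaced-atom: ",
        slotFmt(e$pos), formatAtomSpec(e$spec)), ""))
    paste0("x-link: [", paste(parts, collapse = " | "), "]")
  }
}

#' @describeIn serializeForm serialize a polymer; attributes are emitted in
#'   the fixed order circular, crosslinks, extra, comments
#' @export
setMethod("serializeForm", "Polymer", function(x, ...) {
  units <- vapply(seq_along(x@occurrences), function(i) {
    occ <- x@occurrences[[i]]
    tok <- if (occ$inline) serializeInline(occ)
      else if (nchar(occ$code) == 1L) occ$code
      else paste0("{", occ$code, "}")
    if (i %in% x@nicks) tok <- paste0(tok, ":")
    tok
  }, "")
  out <- paste(units, collapse = "")
  attrs <- character()
  if (isTRUE(x@circular)) attrs <- c(attrs, "circular")
  attrs <- c(attrs, vapply(x@crosslinks, serializeCrosslink, ""))
  if (!is.na(x@extraMass) || !is.na(x@extraCharge)) {
    parts <- c(
      if (!is.na(x@extraMass)) sprintf("mass: %s",
        format(x@extraMass, digits = 15, scientific = FALSE)),
      if (!is.na(x@extraCharge)) sprintf("charge: %d", x@extraCharge))
    attrs <- c(attrs, paste0("extra: [", paste(parts, collapse = " | "), "]"))
  }
  if (length(x@comments) && nzchar(x@comments))
    attrs <- c(attrs, paste0("comments: \"", x@comments, "\""))
  if (length(attrs)) out <- paste(c(out, attrs), collapse = " | ")
  out
})

#' Number of residues of a polymer
#'
#' @param x a [Polymer-class]
#' @return integer; nicks do not count, residues do
#' @export
setMethod("length", "Polymer", function(x) length(x@occurrences))

#' Residue occurrence at a position
#'
#' @param p a [Polymer-class]
#' @param i 1-based residue position
#' @return occurrence list (fields `residue`, `code`, `inline`, `range`,
#'   `comments`)
#' @export
residueAt <- function(p, i) {
  stopifnot(is(p, "Polymer"))
  n <- length(p)
  if (!is.numeric(i) || length(i) != 1L || is.na(i) || i < 1L || i > n)
    stop(errorCondition(sprintf("residue position %s out of range 1..%d",
      as.character(i), n), class = c("mf_range_error", "mf_error")))
  p@occurrences[[as.integer(i)]]
}

setMethod("show", "Polymer", function(object) {
  cat(sprintf("Polymer (%s alphabet): %d residues%s%s%s\n  %s\n",
    object@alphabet@type, length(object),
    if (length(object@nicks)) sprintf(", %d nick(s)", length(object@nicks)) else "",
    if (length(object@crosslinks)) sprintf(", %d crosslink(s)",
      length(object@crosslinks)) else "",
    if (isTRUE(object@circular)) ", circular" else "",
    serializeForm(object)))
})

#' Construct a polymer programmatically
#'
#' @param codes character vector of residue codes (resolved in `alphabet`)
#' @param alphabet an [Alphabet-class] or fixture name
#' @param nicks integer nick positions
#' @param crosslinks list of `list(type=, l=, r=)` crosslinks
#' @param circular logical
#' @param extraMass,extraCharge optional observed extras
#' @return a [Polymer-class]
#' @export
polymer <- function(codes, alphabet, nicks = integer(), crosslinks = list(),
    circular = FALSE, extraMass = NA_real_, extraCharge = NA_integer_) {
  if (is.character(alphabet)) alphabet <- builtinAlphabet(alphabet)
  occurrences <- lapply(codes, function(code) {
    list(residue = getResidue(alphabet, code), code = code, inline = FALSE,
      smiles = NULL, range = NULL, comments = NULL)
  })
  crosslinks <- lapply(crosslinks, function(xl) {
    base <- list(type = NA_character_, l = NA_integer_, r = NA_integer_,
      lBondAtoms = list(), rBondAtoms = list(),
      lDisplacedAtoms = list(), rDisplacedAtoms = list())
    base[names(xl)] <- xl
    base$l <- as.integer(base$l); base$r <- as.integer(base$r)
    base
  })
  new("Polymer", alphabet = alphabet, occurrences = occurrences,
    nicks = as.integer(nicks), crosslinks = crosslinks,
    circular = circular, extraMass = extraMass,
    extraCharge = as.integer(extraCharge), comments = character())
}
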