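# Semantic validation. Rules:
#   V1  every bonded adjacent pair is bondable (left residue has right
#       bond atoms, right residue has left bond atoms)
#   V2  caps only at chain ends: left caps at position 1 or right of a
#       nick; right caps at the last position or left of a nick; no caps
#       anywhere in a circular polymer
#   V3  a circular polymer's closing bond is formable (residue n
#       right-bondable, residue 1 left-bondable)
#   V4  every atom reference (residues, crosslinks) resolves against its
#       structure with the expected element; bond-atom lists pair up
#   V5  every displaced hydrogen has an implicit hydrogen available on its
#       heavy atom (counting all bonds that displace from that atom)
#   V6  crosslink residue coordinates lie within the sequence (and, for
#       complexes, subunit ids exist and copy indices are within the
#       stoichiometry)
#   V7  ontology crosslinks respect their allowed residue codes
#   V8  no atom is consumed by two bonds (backbone/crosslink conflicts)
#   V9  position-uncertainty ranges lie within the sequence and bracket
#       the anchor position

finding <- function(severity, rule, location, message) {
  data.frame(severity = severity, rule = rule, location = location,
    message = message, stringsAsFactors = FALSE)
}

emptyFindings <- function() {
  data.frame(severity = character(), rule = character(),
    location = character(), message = character(), stringsAsFactors = FALSE)
}

validationReport <- function(findings) {
  if (is.null(findings) || length(findings) == 0L) findings <- emptyFindings()
  else if (is.list(findings) && !is.data.frame(findings))
    findings <- do.call(rbind, c(list(emptyFindings()), findings))
  new("ValidationReport", findings = findings)
}

#' Accessors for validation reports
#'
#' @param report a [ValidationReport-class]
#' @return `vErrors()`/`vWarnings()`: data.frames of findings;
#'   `isClean()`: TRUE when the report carries no errors (warnings allowed)
#' @export
vErrors <- function(report) {
  report@findings[report@findings$severity == "error", , drop = FALSE]
}

#' @rdname vErrors
#' @export
vWarnings <- function(report) {
  report@findings[report@findings$severity == "warning", , drop = FALSE]
}

#' @rdname vErrors
#' @export
isClean <- function(report) nrow(vErrors(report)) == 0L

setMethod("show", "ValidationReport", function(object) {
  e <- vErrors(object); w <- vWarnings(object)
  cat(sprintf("ValidationReport: %d error(s), %d warning(s)\n", nrow(e), nrow(w)))
  f <- object@findings
  for (i in seq_len(nrow(f)))
    cat(sprintf("  [%s %s] %s: %s\n", f$severity[i], f$rule[i], f$location[i],
      f$message[i]))
})

#' Render a validation report as line-oriented text or JSON
#'
#' @param report a [ValidationReport-class]
#' @param format `"text"` or `"json"`
#' @return character
#' @export
formatReport <- function(report, format = c("text", "json")) {
  format <- match.arg(format)
  f <- report@findings
  if (format == "json")
    return(as.character(jsonlite::toJSON(list(
      clean = isClean(report),
      errors = vErrors(report)[c("rule", "location", "message")],
      warnings = vWarnings(report)[c("rule", "location", "message")]),
      auto_unbox = TRUE, pretty = TRUE)))
  if (nrow(f) == 0L) return("clean")
  paste(sprintf("%s %s at %s: %s", f$severity, f$rule, f$location, f$message),
    collapse = "\n")
}

# resolve one atom spec against a residue structure, producing a finding
# instead of raising; returns NULL when the reference is fine
checkSpec <- function(g, spec, location, role = "atom") {
  n <- numAtoms(g)
  if (spec$index < 1L || spec$index > n)
    return(finding("error", "V4", location,
      sprintf("%s reference %s: atom index out of range 1..%d", role,
        formatAtomSpec(spec), n)))
  if (spec$element != "H") {
    found <- g@atoms$element[spec$index]
    if (!identical(found, spec$element))
      return(finding("error", "V4", location,
        sprintf("%s reference %s: element mismatch (expected %s, found %s)",
          role, formatAtomSpec(spec), spec$element, found)))
  }
  NULL
}

# Bond events of one chain: backbone bonds between adjacent non-nicked
# residues (plus the closing bond when circular) and intra-chain
# crosslinks. Each event carries paired bond refs and displaced refs,
# where a ref is list(inst = instance index, spec = atom spec). `labeller`
# maps a local residue position to a location string.
chainEvents <- function(occurrences, nicks, circular, crosslinks, ontology,
    offset = 0L, labeller = function(i) sprintf("residue %d", i)) {
  n <- length(occurrences)
  events <- list()
  addBackbone <- function(i, j) {
    ri <- occurrences[[i]]$residue; rj <- occurrences[[j]]$residue
    events[[length(events) + 1L]] <<- list(
      kind = "backbone",
      location = sprintf("%s-%s", labeller(i), labeller(j)),
      lInst = offset + i, rInst = offset + j,
      lBond = ri@rBondAtoms, rBond = rj@lBondAtoms,
      lDisp = ri@rDisplacedAtoms, rDisp = rj@lDisplacedAtoms)
  }
  if (n > 1L) for (i in seq_len(n - 1L)) if (!i %in% nicks) addBackbone(i, i + 1L)
  if (circular && !(n %in% nicks) && n > 1L) addBackbone(n, 1L)
  for (k in seq_along(crosslinks)) {
    xl <- crosslinks[[k]]
    loc <- sprintf("crosslink %d", k)
    if (!is.na(xl$type)) {
      ty <- getCrosslinkType(ontology, xl$type)
      events[[length(events) + 1L]] <- list(
        kind = "crosslink", type = xl$type, location = loc,
        lInst = offset + xl$l, rInst = offset + xl$r,
        lBond = ty@lBondAtoms, rBond = ty@rBondAtoms,
        lDisp = ty@lDisplacedAtoms, rDisp = ty@rDisplacedAtoms)
    } else {
      # explicit refs carry their own residue positions; keep them per-ref
      events[[length(events) + 1L]] <- list(
        kind = "crosslink", type = NA_character_, location = loc,
        lRefs = lapply(xl$lBondAtoms, function(e)
          list(inst = offset + e$pos, spec = e$spec)),
        rRefs = lapply(xl$rBondAtoms, function(e)
          list(inst = offset + e$pos, spec = e$spec)),
        dispRefs = lapply(c(xl$lDisplacedAtoms, xl$rDisplacedAtoms),
          function(e) list(inst = offset + e$pos, spec = e$spec)))
    }
  }
  events
}

# normalize an event into flat lists of paired bond refs and displaced refs
eventRefs <- function(ev) {
  if (!is.null(ev$lRefs)) {
    list(lRefs = ev$lRefs, rRefs = ev$rRefs, dispRefs = ev$dispRefs,
      location = ev$location)
  } else {
    list(
      lRefs = lapply(ev$lBond, function(s) list(inst = ev$lInst, spec = s)),
      rRefs = lapply(ev$rBond, function(s) list(inst = ev$rInst, spec = s)),
      dispRefs = c(
        lapply(ev$lDisp, function(s) list(inst = ev$lInst, spec = s)),
        lapply(ev$rDisp, function(s) list(inst = ev$rInst, spec = s))),
      location = ev$location)
  }
}

# shared V4/V5/V8 checks over a set of instances (structure graphs) and
# bond events; instLabel maps instance index to a location string
checkEvents <- function(events, graphs, instLabel) {
  out <- list()
  refLoc <- function(ref, evloc) sprintf("%s (%s)", evloc, instLabel(ref$inst))
  # V4: resolvable refs, no H bond atoms, paired list lengths
  ok <- TRUE
  for (ev in events) {
    er <- eventRefs(ev)
    for (ref in c(er$lRefs, er$rRefs)) {
      if (ref$spec$element == "H") {
        out[[length(out) + 1L]] <- finding("error", "V4",
          refLoc(ref, er$location),
          "an implicit hydrogen cannot serve as a bond atom")
        ok <- FALSE
        next
      }
      fnd <- checkSpec(graphs[[ref$inst]], ref$spec, refLoc(ref, er$location),
        "bond-atom")
      if (!is.null(fnd)) { out[[length(out) + 1L]] <- fnd; ok <- FALSE }
    }
    for (ref in er$dispRefs) {
      fnd <- checkSpec(graphs[[ref$inst]], ref$spec, refLoc(ref, er$location),
        "displaced-atom")
      if (!is.null(fnd)) { out[[length(out) + 1L]] <- fnd; ok <- FALSE }
    }
    if (length(er$lRefs) != length(er$rRefs)) {
      out[[length(out) + 1L]] <- finding("error", "V4", er$location,
        sprintf("bond-atom lists do not pair up (%d left vs %d right)",
          length(er$lRefs), length(er$rRefs)))
      ok <- FALSE
    }
  }
  if (!ok) return(out)
  # V5: hydrogen availability per heavy atom
  hneed <- new.env(parent = emptyenv())
  for (ev in events) {
    er <- eventRefs(ev)
    for (ref in er$dispRefs) {
      if (ref$spec$element != "H") next
      key <- paste(ref$inst, ref$spec$index)
      cur <- mget(key, hneed, ifnotfound = list(list(n = 0L, ref = ref,
        loc = er$location)))[[1]]
      cur$n <- cur$n + 1L
      assign(key, cur, hneed)
    }
  }
  for (key in ls(hneed)) {
    cur <- get(key, hneed)
    avail <- graphs[[cur$ref$inst]]@atoms$hcount[cur$ref$spec$index]
    if (cur$n > avail)
      out[[length(out) + 1L]] <- finding("error", "V5",
        sprintf("%s (%s)", cur$loc, instLabel(cur$ref$inst)),
        sprintf("displacing %d hydrogen(s) from atom %s%d but only %d available",
          cur$n, graphs[[cur$ref$inst]]@atoms$element[cur$ref$spec$index],
          cur$ref$spec$index, avail))
  }
  # V8: no bond atom consumed twice
  used <- new.env(parent = emptyenv())
  for (ev in events) {
    er <- eventRefs(ev)
    for (ref in c(er$lRefs, er$rRefs)) {
      key <- paste(ref$inst, ref$spec$index)
      prev <- mget(key, used, ifnotfound = list(NULL))[[1]]
      if (!is.null(prev)) {
        out[[length(out) + 1L]] <- finding("error", "V8",
          sprintf("%s (%s)", er$location, instLabel(ref$inst)),
          sprintf("atom %s%d already consumed by a bond at %s",
            ref$spec$element, ref$spec$index, prev))
      } else assign(key, er$location, used)
    }
  }
  out
}

#' Validate a polymer semantically
#'
#' Applies rules V1-V9 (see the source header of `validate.R` and the
#' package vignette): bondability of adjacent residues, cap placement,
#' circular-closure bondability, atom-reference resolution, hydrogen
#' availability for displacements, crosslink coordinates and allowed
#' residues, atom-consumption conflicts, and position-uncertainty ranges.
#' A polymer assembles successfully if and only if its report is clean.
#'
#' @param p a parsed [Polymer-class]
#' @param ontology a [CrosslinkOntology-class]
#' @return a [ValidationReport-class]; findings, not exceptions
#' @examples
#' isClean(validatePolymer(parsePolymer("AC{SEC}", "protein")))
#' @export
validatePolymer <- function(p, ontology = builtinOntology()) {
  stopifnot(is(p, "Polymer"))
  n <- length(p)
  out <- list()
  resAt <- function(i) p@occurrences[[i]]$residue
  codeAt <- function(i) p@occurrences[[i]]$code
  loc <- function(i) sprintf("residue %d", i)
  # V1: bondable adjacent pairs
  pairs <- if (n > 1L) lapply(setdiff(seq_len(n - 1L), p@nicks),
    function(i) c(i, i + 1L)) else list()
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    if (isRightCap(resAt(i)))
      out[[length(out) + 1L]] <- finding("error", "V1",
        sprintf("residue %d-%d", i, j),
        sprintf("residue %d (%s) has no right bond atoms and cannot bond residue %d",
          i, codeAt(i), j))
    if (isLeftCap(resAt(j)))
      out[[length(out) + 1L]] <- finding("error", "V1",
        sprintf("residue %d-%d", i, j),
        sprintf("residue %d (%s) has no left bond atoms and cannot bond residue %d",
          j, codeAt(j), i))
  }
  # V2: cap placement
  for (i in seq_len(n)) {
    r <- resAt(i)
    if (isLeftCap(r)) {
      okpos <- !p@circular && (i == 1L || (i - 1L) %in% p@nicks)
      if (!okpos)
        out[[length(out) + 1L]] <- finding("error", "V2", loc(i),
          sprintf("left cap %s only allowed at position 1 or right of a nick%s",
            codeAt(i), if (p@circular) " (never in a circular polymer)" else ""))
    }
    if (isRightCap(r)) {
      okpos <- !p@circular && (i == n || i %in% p@nicks)
      if (!okpos)
        out[[length(out) + 1L]] <- finding("error", "V2", loc(i),
          sprintf("right cap %s only allowed at the final position or left of a nick%s",
            codeAt(i), if (p@circular) " (never in a circular polymer)" else ""))
    }
  }
  # V3: circular closure
  if (p@circular && !(n %in% p@nicks)) {
    if (isRightCap(resAt(n)))
      out[[length(out) + 1L]] <- finding("error", "V3", loc(n),
        "circular polymer: final residue has no right bond atoms for the closing bond")
    if (isLeftCap(resAt(1L)))
      out[[length(out) + 1L]] <- finding("error", "V3", loc(1L),
        "circular polymer: first residue has no left bond atoms for the closing bond")
  }
  # V6: crosslink coordinates; V7: allowed residues
  xl_ok <- logical(length(p@crosslinks))
  for (k in seq_along(p@crosslinks)) {
    xl <- p@crosslinks[[k]]
    xloc <- sprintf("crosslink %d", k)
    positions <- if (!is.na(xl$type)) c(xl$l, xl$r) else
      vapply(c(xl$lBondAtoms, xl$rBondAtoms, xl$lDisplacedAtoms,
        xl$rDisplacedAtoms), `[[`, 0L, "pos")
    bad <- positions[positions < 1L | positions > n]
    if (length(bad)) {
      out[[length(out) + 1L]] <- finding("error", "V6", xloc,
        sprintf("residue coordinate(s) %s beyond the sequence length %d",
          paste(unique(bad), collapse = ", "), n))
      next
    }
    xl_ok[k] <- TRUE
    if (!is.na(xl$type)) {
      ty <- getCrosslinkType(ontology, xl$type)
      if (length(ty@allowedL) && !codeAt(xl$l) %in% ty@allowedL)
        out[[length(out) + 1L]] <- finding("error", "V7", xloc,
          sprintf("%s does not allow residue %s in its left slot (allowed: %s)",
            xl$type, codeAt(xl$l), paste(ty@allowedL, collapse = ", ")))
      if (length(ty@allowedR) && !codeAt(xl$r) %in% ty@allowedR)
        out[[length(out) + 1L]] <- finding("error", "V7", xloc,
          sprintf("%s does not allow residue %s in its right slot (allowed: %s)",
            xl$type, codeAt(xl$r), paste(ty@allowedR, collapse = ", ")))
    }
  }
  # V9: uncertainty ranges
  for (i in seq_len(n)) {
    rg <- p@occurrences[[i]]$range
    if (is.null(rg)) next
    if (rg[1] > rg[2] || rg[1] < 1L || rg[2] > n || i < rg[1] || i > rg[2])
      out[[length(out) + 1L]] <- finding("error", "V9", loc(i),
        sprintf("position range %d-%d must lie within 1..%d and bracket position %d",
          rg[1], rg[2], n, i))
  }
  # V4/V5/V8 need resolvable coordinates: restrict to in-range crosslinks
  events <- chainEvents(p@occurrences, p@nicks, p@circular,
    p@crosslinks[xl_ok], ontology)
  graphs <- lapply(p@occurrences, function(occ) occ$residue@structure)
  out <- c(out, checkEvents(events, graphs, loc))
  # residue-level specs of inline residues (alphabet residues were
  # resolved at load time, but re-checking is cheap and uniform)
  for (i in seq_len(n)) {
    r <- resAt(i)
    for (spec in c(r@lBondAtoms, r@rBondAtoms, r@lDisplacedAtoms,
        r@rDisplacedAtoms)) {
      fnd <- checkSpec(r@structure, spec, loc(i), "residue atom")
      if (!is.null(fnd)) out[[length(out) + 1L]] <- fnd
    }
  }
  f <- if (length(out)) unique(do.call(rbind, out)) else emptyFindings()
  # nick/crosslink coexistence is legal but worth flagging
  if (length(p@nicks) && any(xl_ok)) {
    for (k in which(xl_ok)) {
      xl <- p@crosslinks[[k]]
      lo <- min(xl$l, xl$r); hi <- max(xl$l, xl$r)
      if (any(p@nicks >= lo & p@nicks < hi))
        f <- rbind(f, finding("warning", "W1", sprintf("crosslink %d", k),
          "crosslink spans a nick"))
    }
  }
  validationReport(f)
}

#' Validate a complex semantically
#'
#' Runs [validatePolymer()] on every polymeric subunit and applies the
#' crosslink rules (V4-V8) at complex scope: subunit ids must exist, copy
#' indices must not exceed stoichiometries, residue coordinates must lie
#' within the subunit, atom references must resolve, allowed-residue
#' constraints must hold, and no atom may be consumed twice across all
#' copies.
#'
#' @param x a [ComplexForm-class] with subunit structures attached
#' @param ontology a [CrosslinkOntology-class]
#' @return a [ValidationReport-class]
#' @export
validateComplex <- function(x, ontology = builtinOntology()) {
  stopifnot(is(x, "ComplexForm"))
  out <- list()
  ids <- vapply(x@subunits, `[[`, "", "id")
  stoich <- stats::setNames(vapply(x@subunits, `[[`, 0L, "stoichiometry"), ids)
  for (s in x@subunits) {
    if (is.null(s$structure)) {
      out[[length(out) + 1L]] <- finding("error", "V4",
        sprintf("subunit %s", s$id),
        "no structure attached; semantic validation requires one")
    } else if (is(s$structure, "Polymer")) {
      rep_s <- validatePolymer(s$structure, ontology)
      f <- rep_s@findings
      if (nrow(f)) {
        f$location <- sprintf("subunit %s: %s", s$id, f$location)
        out[[length(out) + 1L]] <- f
      }
    }
  }
  lay <- tryCatch(complexLayout(x), error = function(e) NULL)
  for (k in seq_along(x@crosslinks)) {
    xl <- x@crosslinks[[k]]
    xloc <- sprintf("crosslink %d", k)
    slots <- if (!is.na(xl$type)) list(xl$l, xl$r) else
      lapply(c(xl$lBondAtoms, xl$rBondAtoms, xl$lDisplacedAtoms,
        xl$rDisplacedAtoms), function(e) e[c("subunit", "copy", "pos")])
    ok <- TRUE
    for (s in slots) {
      if (!s$subunit %in% ids) {
        out[[length(out) + 1L]] <- finding("error", "V6", xloc,
          sprintf("unknown subunit '%s'", s$subunit))
        ok <- FALSE; next
      }
      if (s$copy < 1L || s$copy > stoich[[s$subunit]]) {
        out[[length(out) + 1L]] <- finding("error", "V6", xloc,
          sprintf("copy index %d outside 1..%d for subunit '%s'",
            s$copy, stoich[[s$subunit]], s$subunit))
        ok <- FALSE; next
      }
      st <- x@subunits[[match(s$subunit, ids)]]$structure
      if (is(st, "Polymer") && (s$pos < 1L || s$pos > length(st))) {
        out[[length(out) + 1L]] <- finding("error", "V6", xloc,
          sprintf("residue coordinate %d beyond the length %d of subunit '%s'",
            s$pos, length(st), s$subunit))
        ok <- FALSE
      }
    }
    if (!ok) next
    if (!is.na(xl$type)) {
      if (identical(slotKey(xl$l), slotKey(xl$r)))
        out[[length(out) + 1L]] <- finding("error", "V6", xloc,
          "crosslink endpoints refer to the same residue of the same copy")
      ty <- getCrosslinkType(ontology, xl$type)
      codeOf <- function(s) {
        st <- x@subunits[[match(s$subunit, ids)]]$structure
        if (is(st, "Polymer")) st@occurrences[[s$pos]]$code else NA_character_
      }
      if (length(ty@allowedL) && !isTRUE(codeOf(xl$l) %in% ty@allowedL))
        out[[length(out) + 1L]] <- finding("error", "V7", xloc,
          sprintf("%s does not allow residue %s in its left slot", xl$type,
            codeOf(xl$l)))
      if (length(ty@allowedR) && !isTRUE(codeOf(xl$r) %in% ty@allowedR))
        out[[length(out) + 1L]] <- finding("error", "V7", xloc,
          sprintf("%s does not allow residue %s in its right slot", xl$type,
            codeOf(xl$r)))
    }
  }
  blocked <- length(out) > 0L &&
    any(vapply(out, function(f) any(f$severity == "error"), TRUE))
  if (!blocked && !is.null(lay)) {
    out <- c(out, checkEvents(lay$events, lay$graphs, lay$instLabel))
  }
  f <- if (length(out)) unique(do.call(rbind, out)) else emptyFindings()
  validationReport(f)
}
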