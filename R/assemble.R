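# Assembly of described molecules into molecular graphs, and the property
# calculations (formula, molecular weight, charge) computed on the
# assembled graph.

# layout of a complex: one graph per residue instance (expanded per copy),
# plus all bond events (per-copy backbone + intra-chain crosslinks, and
# inter-subunit crosslinks)
complexLayout <- function(x, ontology = builtinOntology()) {
  graphs <- list()
  meta <- list()
  events <- list()
  instMap <- new.env(parent = emptyenv())   # "id/copy/pos" -> instance index
  for (s in x@subunits) {
    if (is.null(s$structure))
      stop("subunit ", s$id, " has no structure attached")
    for (copy in seq_len(s$stoichiometry)) {
      if (is(s$structure, "Polymer")) {
        p <- s$structure
        offset <- length(graphs)
        for (pos in seq_len(length(p))) {
          graphs[[offset + pos]] <- p@occurrences[[pos]]$residue@structure
          meta[[offset + pos]] <- sprintf("%s(%d) residue %d", s$id, copy, pos)
          assign(paste(s$id, copy, pos, sep = "/"), offset + pos, instMap)
        }
        events <- c(events, chainEvents(p@occurrences, p@nicks, p@circular,
          p@crosslinks, ontology, offset = offset,
          labeller = function(i) sprintf("%s(%d) residue %d", s$id, copy, i)))
      } else if (is(s$structure, "MolecularGraph")) {
        graphs[[length(graphs) + 1L]] <- s$structure
        meta[[length(graphs)]] <- sprintf("%s(%d)", s$id, copy)
        assign(paste(s$id, copy, 1L, sep = "/"), length(graphs), instMap)
      } else stop("subunit ", s$id, " has an unsupported structure class")
    }
  }
  lookup <- function(slot) {
    key <- paste(slot$subunit, slot$copy, slot$pos, sep = "/")
    idx <- mget(key, instMap, ifnotfound = list(NULL))[[1]]
    if (is.null(idx)) stop("unresolvable coordinate ", key)
    idx
  }
  for (k in seq_along(x@crosslinks)) {
    xl <- x@crosslinks[[k]]
    loc <- sprintf("complex crosslink %d", k)
    if (!is.na(xl$type)) {
      ty <- getCrosslinkType(ontology, xl$type)
      events[[length(events) + 1L]] <- list(
        kind = "crosslink", type = xl$type, location = loc,
        lInst = lookup(xl$l), rInst = lookup(xl$r),
        lBond = ty@lBondAtoms, rBond = ty@rBondAtoms,
        lDisp = ty@lDisplacedAtoms, rDisp = ty@rDisplacedAtoms)
    } else {
      events[[length(events) + 1L]] <- list(
        kind = "crosslink", type = NA_character_, location = loc,
        lRefs = lapply(xl$lBondAtoms, function(e)
          list(inst = lookup(e), spec = e$spec)),
        rRefs = lapply(xl$rBondAtoms, function(e)
          list(inst = lookup(e), spec = e$spec)),
        dispRefs = lapply(c(xl$lDisplacedAtoms, xl$rDisplacedAtoms),
          function(e) list(inst = lookup(e), spec = e$spec)))
    }
  }
  list(graphs = graphs, events = events,
    instLabel = function(i) meta[[i]])
}

# realize instances + bond events as one molecular graph
assembleLayout <- function(graphs, events) {
  counts <- vapply(graphs, numAtoms, 0L)
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  element <- unlist(lapply(graphs, function(g) g@atoms$element))
  charge <- unlist(lapply(graphs, function(g) g@atoms$charge))
  hcount <- unlist(lapply(graphs, function(g) g@atoms$hcount))
  b_a <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]@bonds$a + offsets[i]))
  b_b <- unlist(lapply(seq_along(graphs), function(i)
    graphs[[i]]@bonds$b + offsets[i]))
  b_ord <- unlist(lapply(graphs, function(g) g@bonds$order))
  deleted <- logical(length(element))
  gidx <- function(ref) offsets[ref$inst] + ref$spec$index
  for (ev in events) {
    er <- eventRefs(ev)
    for (ref in er$dispRefs) {
      gi <- gidx(ref)
      if (ref$spec$element == "H") {
        hcount[gi] <- hcount[gi] - 1L
        if (hcount[gi] < 0L)
          stop("assembly: no hydrogen left to displace at ", er$location)
        charge[gi] <- charge[gi] + ref$spec$chargeDelta
      } else {
        deleted[gi] <- TRUE
      }
    }
    if (length(er$lRefs) != length(er$rRefs))
      stop("assembly: unpaired bond-atom lists at ", er$location)
    for (k in seq_along(er$lRefs)) {
      la <- gidx(er$lRefs[[k]]); ra <- gidx(er$rRefs[[k]])
      charge[la] <- charge[la] + er$lRefs[[k]]$spec$chargeDelta
      charge[ra] <- charge[ra] + er$rRefs[[k]]$spec$chargeDelta
      b_a <- c(b_a, la); b_b <- c(b_b, ra); b_ord <- c(b_ord, "single")
    }
  }
  if (any(deleted)) {
    keepBond <- !(deleted[b_a] | deleted[b_b])
    b_a <- b_a[keepBond]; b_b <- b_b[keepBond]; b_ord <- b_ord[keepBond]
    remap <- cumsum(!deleted)
    b_a <- remap[b_a]; b_b <- remap[b_b]
    element <- element[!deleted]; charge <- charge[!deleted]
    hcount <- hcount[!deleted]
  }
  molecularGraph(
    data.frame(element = element, charge = charge, hcount = hcount,
      stringsAsFactors = FALSE),
    data.frame(a = b_a, b = b_b, order = b_ord, stringsAsFactors = FALSE))
}

requireClean <- function(report, what) {
  if (!isClean(report)) {
    e <- vErrors(report)
    stop(what, " fails validation:\n",
      paste(sprintf("  %s at %s: %s", e$rule, e$location, e$message),
        collapse = "\n"))
  }
  invisible(TRUE)
}

#' @describeIn assemble assemble a polymer (backbone bonds between
#'   adjacent non-nicked residues, the closing bond when circular, and all
#'   intra-chain crosslinks)
#' @param ontology a [CrosslinkOntology-class]
#' @param check validate first and stop on errors (default TRUE)
#' @export
setMethod("assemble", "Polymer", function(x, ontology = builtinOntology(),
    check = TRUE, ...) {
  if (check) requireClean(validatePolymer(x, ontology), "polymer")
  graphs <- lapply(x@occurrences, function(occ) occ$residue@structure)
  events <- chainEvents(x@occurrences, x@nicks, x@circular, x@crosslinks,
    ontology)
  assembleLayout(graphs, events)
})

#' @describeIn assemble assemble a complex (each subunit expanded to its
#'   stoichiometry; inter-subunit crosslinks realized across copies)
#' @export
setMethod("assemble", "ComplexForm", function(x, ontology = builtinOntology(),
    check = TRUE, ...) {
  if (check) requireClean(validateComplex(x, ontology), "complex")
  lay <- complexLayout(x, ontology)
  assembleLayout(lay$graphs, lay$events)
})

#' @describeIn getFormula formula of the assembled polymer
#' @param ontology a [CrosslinkOntology-class]
#' @export
setMethod("getFormula", "Polymer", function(x, ontology = builtinOntology(), ...) {
  getFormula(assemble(x, ontology, ...))
})

#' @describeIn getFormula formula of the assembled complex
#' @export
setMethod("getFormula", "ComplexForm", function(x, ontology = builtinOntology(), ...) {
  getFormula(assemble(x, ontology, ...))
})

# extra observed mass/charge contribute to MW and charge but cannot
# contribute elements to the formula
#' @describeIn getMolWeight molecular weight of the assembled polymer plus
#'   any recorded extra observed mass
#' @param ontology a [CrosslinkOntology-class]
#' @export
setMethod("getMolWeight", "Polymer", function(x, ontology = builtinOntology(), ...) {
  mw <- getMolWeight(assemble(x, ontology, ...))
  if (!is.na(x@extraMass)) mw <- mw + x@extraMass
  mw
})

#' @describeIn getMolWeight molecular weight of the assembled complex
#' @export
setMethod("getMolWeight", "ComplexForm", function(x, ontology = builtinOntology(), ...) {
  getMolWeight(assemble(x, ontology, ...))
})

#' @describeIn getCharge net charge of the assembled polymer plus any
#'   recorded extra observed charge
#' @param ontology a [CrosslinkOntology-class]
#' @export
setMethod("getCharge", "Polymer", function(x, ontology = builtinOntology(), ...) {
  ch <- getCharge(assemble(x, ontology, ...))
  if (!is.na(x@extraCharge)) ch <- ch + x@extraCharge
  as.integer(ch)
})

#' @describeIn getCharge net charge of the assembled complex
#' @export
setMethod("getCharge", "ComplexForm", function(x, ontology = builtinOntology(), ...) {
  getCharge(assemble(x, ontology, ...))
})

#' @describeIn exportSmiles SMILES of the assembled polymer
#' @param ontology a [CrosslinkOntology-class]
#' @export
setMethod("exportSmiles", "Polymer", function(x, ontology = builtinOntology(), ...) {
  writeSmiles(assemble(x, ontology, ...))
})

#' @describeIn exportSmiles SMILES of the assembled complex
#' @export
setMethod("exportSmiles", "ComplexForm", function(x, ontology = builtinOntology(), ...) {
  writeSmiles(assemble(x, ontology, ...))
})
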