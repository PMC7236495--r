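# Minimal cheminformatics core: a SMILES subset sufficient for residue
# structures (atoms, brackets with explicit H/charge, bond symbols - = # :,
# branches, ring closures including %nn, dots, aromatic lowercase atoms).
# Stereochemistry is not supported; bracket isotopes parse but are ignored
# with a warning.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMENTS <- c("b", "c", "n", "o", "p", "s", "se", "as")

# standard default valences, lowest first
.valences <- list(B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L, Se = c(2L, 4L, 6L),
  As = c(3L, 5L))

smilesError <- function(msg, pos) {
  stop(errorCondition(sprintf("SMILES parse error at character %d: %s", pos, msg),
    class = c("mf_smiles_error", "mf_error")))
}

#' Construct a molecular graph directly
#'
#' Low-level constructor; most users obtain graphs from [parseSmiles()].
#'
#' @param atoms data.frame with columns `element`, `charge`, `hcount`
#' @param bonds data.frame with columns `a`, `b`, `order`
#' @return a [MolecularGraph-class]
#' @export
molecularGraph <- function(atoms = data.frame(element = character(),
    charge = integer(), hcount = integer()),
    bonds = data.frame(a = integer(), b = integer(), order = character())) {
  atoms <- data.frame(element = as.character(atoms$element),
    charge = as.integer(atoms$charge), hcount = as.integer(atoms$hcount),
    stringsAsFactors = FALSE)
  if (nrow(bonds)) {
    bonds <- data.frame(a = pmin(as.integer(bonds$a), as.integer(bonds$b)),
      b = pmax(as.integer(bonds$a), as.integer(bonds$b)),
      order = as.character(bonds$order), stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(a = integer(), b = integer(), order = character())
  }
  new("MolecularGraph", atoms = atoms, bonds = bonds)
}

numAtoms <- function(g) nrow(g@atoms)

#' Parse a SMILES string into a molecular graph
#'
#' Atoms are stored in order of first appearance in the string; that order
#' defines the atom coordinates used throughout the package. Implicit
#' hydrogens of organic-subset atoms are filled by the standard
#' default-valence rule (B 3; C 4; N 3/5; O 2; P 3/5; S 2/4/6; halogens 1);
#' bracket atoms carry exactly the hydrogens they declare. Aromatic
#' (lowercase) input is kekulized by alternating-bond assignment over each
#' aromatic system; failure to kekulize is an error.
#'
#' @param text single non-empty SMILES string
#' @return a [MolecularGraph-class]
#' @examples
#' g <- parseSmiles("NCC(O)=O")   # glycine
#' formulaString(getFormula(g))   # "C2H5NO2"
#' @export
parseSmiles <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    smilesError("empty input", 1L)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  element <- character(); charge <- integer(); hcount <- integer()
  bracket <- logical(); aromatic <- logical(); atpos <- integer()
  b_a <- integer(); b_b <- integer(); b_ord <- character()
  addBond <- function(a, b, ord, pos) {
    if (a == b) smilesError("self-bond", pos)
    if (any((b_a == min(a, b)) & (b_b == max(a, b))))
      smilesError("duplicate bond between the same atom pair", pos)
    b_a <<- c(b_a, min(a, b)); b_b <<- c(b_b, max(a, b)); b_ord <<- c(b_ord, ord)
  }
  prev <- NA_integer_
  stack <- integer()
  pending <- NA_character_   # explicit bond symbol awaiting next atom
  pending_pos <- NA_integer_
  rings <- list()            # ring-closure number -> list(atom, order, pos)
  i <- 1L
  newAtom <- function(el, ch, hc, br, ar, pos) {
    element <<- c(element, el); charge <<- c(charge, ch); hcount <<- c(hcount, hc)
    bracket <<- c(bracket, br); aromatic <<- c(aromatic, ar); atpos <<- c(atpos, pos)
    idx <- length(element)
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord)) ord <- if (aromatic[prev] && ar) "aromatic" else "single"
      addBond(prev, idx, ord, pos)
    } else if (!is.na(pending)) {
      smilesError("bond symbol with no preceding atom", pending_pos)
    }
    pending <<- NA_character_
    prev <<- idx
  }
  ringClosure <- function(num, pos) {
    if (is.na(prev)) smilesError("ring-closure digit with no preceding atom", pos)
    key <- as.character(num)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, order = pending, pos = pos)
    } else {
      open <- rings[[key]]
      ord <- pending
      if (!is.na(open$order) && !is.na(ord) && open$order != ord)
        smilesError("conflicting bond orders on ring closure", pos)
      if (is.na(ord)) ord <- open$order
      if (is.na(ord))
        ord <- if (aromatic[open$atom] && aromatic[prev]) "aromatic" else "single"
      addBond(open$atom, prev, ord, pos)
      rings[[key]] <<- NULL
    }
    pending <<- NA_character_
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "(") {
      if (is.na(prev)) smilesError("branch with no preceding atom", i)
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (length(stack) == 0L) smilesError("unbalanced parentheses", i)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":")) {
      pending <- c(`-` = "single", `=` = "double", `#` = "triple",
        `:` = "aromatic")[[ch]]
      pending_pos <- i
      i <- i + 1L; next
    }
    if (ch %in% c("/", "\\")) smilesError("stereochemistry is not supported", i)
    if (ch == ".") {
      if (!is.na(pending)) smilesError("bond symbol before '.'", pending_pos)
      prev <- NA_integer_; i <- i + 1L; next
    }
    if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        smilesError("'%' must be followed by two digits", i)
      ringClosure(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L; next
    }
    if (grepl("^[0-9]$", ch)) { ringClosure(as.integer(ch), i); i <- i + 1L; next }
    if (ch == "[") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= n) { if (chars[j] == "]") { close <- j; break }; j <- j + 1L }
      if (is.na(close)) smilesError("unclosed bracket atom", i)
      body <- substr(text, i + 1L, close - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]+)?([A-Z][a-z]?|[a-z][a-z]?)(@+)?(H[0-9]*)?([+-][0-9]*|\\++|-+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L || !nzchar(m[3]))
        smilesError(paste0("malformed bracket atom '[", body, "]'"), i)
      if (nzchar(m[4])) smilesError("stereochemistry is not supported", i)
      if (nzchar(m[2]))
        warning("isotope label ignored in bracket atom [", body, "]",
          call. = FALSE)
      el <- m[3]
      ar <- el %in% AROMATIC_ELEMENTS
      if (ar) el <- paste0(toupper(substr(el, 1, 1)), substr(el, 2, nchar(el)))
      if (!el %in% names(elementWeights()))
        smilesError(paste0("unknown element '", el, "'"), i)
      hc <- 0L
      if (nzchar(m[5])) {
        hc <- if (m[5] == "H") 1L else as.integer(sub("^H", "", m[5]))
      }
      chg <- 0L
      if (nzchar(m[6])) {
        cs <- m[6]
        if (grepl("^[+-][0-9]+$", cs)) {
          chg <- as.integer(cs)
        } else {
          chg <- nchar(cs) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
        }
      }
      newAtom(el, chg, hc, TRUE, ar, i)
      i <- close + 1L
      next
    }
    # organic-subset atom (two-char halogens first)
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) { newAtom(two, 0L, NA_integer_, FALSE, FALSE, i); i <- i + 2L; next }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      newAtom(ch, 0L, NA_integer_, FALSE, FALSE, i); i <- i + 1L; next
    }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      newAtom(toupper(ch), 0L, NA_integer_, FALSE, TRUE, i); i <- i + 1L; next
    }
    smilesError(paste0("unexpected character '", ch, "'"), i)
  }
  if (length(stack)) smilesError("unbalanced parentheses", n)
  if (length(rings)) {
    r <- rings[[1]]
    smilesError(paste0("dangling ring closure '", names(rings)[1], "'"), r$pos)
  }
  if (!is.na(pending)) smilesError("trailing bond symbol", pending_pos)
  if (length(element) == 0L) smilesError("no atoms", 1L)

  bonds <- data.frame(a = b_a, b = b_b, order = b_ord, stringsAsFactors = FALSE)
  kek <- kekulizeBonds(element, charge, hcount, bracket, aromatic, bonds, atpos)
  bonds <- kek$bonds

  # fill implicit hydrogens for organic-subset (non-bracket) atoms
  ordnum <- c(single = 1L, double = 2L, triple = 3L)
  bsum <- integer(length(element))
  if (nrow(bonds)) {
    o <- ordnum[bonds$order]
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$a[k]] <- bsum[bonds$a[k]] + o[k]
      bsum[bonds$b[k]] <- bsum[bonds$b[k]] + o[k]
    }
  }
  for (a in seq_along(element)) {
    if (bracket[a]) next
    vals <- .valences[[element[a]]]
    fit <- vals[vals >= bsum[a]]
    if (length(fit) == 0L)
      smilesError(paste0("valence overflow on ", element[a], " (bond order sum ",
        bsum[a], ")"), atpos[a])
    hcount[a] <- fit[1] - bsum[a]
  }
  molecularGraph(
    data.frame(element = element, charge = charge, hcount = hcount,
      stringsAsFactors = FALSE),
    bonds)
}

# Kekulize aromatic systems: each aromatic atom whose bond-order sum
# (aromatic bonds counted as single) plus declared hydrogens falls short of
# its default valence must receive exactly one double bond; a perfect
# matching over the aromatic bonds between such atoms is found by
# backtracking. Remaining aromatic bonds become single.
kekulizeBonds <- function(element, charge, hcount, bracket, aromatic, bonds, atpos) {
  arom_bonds <- which(bonds$order == "aromatic")
  if (length(arom_bonds) == 0L) {
    if (any(aromatic)) {
      a <- which(aromatic)[1]
      smilesError("aromatic atom with no aromatic bonds", atpos[a])
    }
    return(list(bonds = bonds))
  }
  ordnum <- c(single = 1L, double = 2L, triple = 3L, aromatic = 1L)
  nA <- length(element)
  bsum <- integer(nA)
  o <- ordnum[bonds$order]
  for (k in seq_len(nrow(bonds))) {
    bsum[bonds$a[k]] <- bsum[bonds$a[k]] + o[k]
    bsum[bonds$b[k]] <- bsum[bonds$b[k]] + o[k]
  }
  needy <- logical(nA)
  for (a in seq_len(nA)) {
    if (!aromatic[a]) next
    vals <- .valences[[element[a]]]
    if (is.null(vals)) smilesError(paste0("cannot kekulize element ", element[a]), atpos[a])
    val <- vals[1]
    # protonated aromatic N/P (e.g. pyridinium) gains a bond
    if (element[a] %in% c("N", "P")) val <- val + max(0L, charge[a])
    h <- if (bracket[a]) hcount[a] else 0L
    needy[a] <- (val - bsum[a] - h) >= 1L
  }
  need_idx <- which(needy)
  if (length(need_idx) %% 2L == 1L)
    smilesError("cannot kekulize aromatic system (odd number of unsaturated atoms)",
      atpos[need_idx[1]])
  # candidate edges: aromatic bonds joining two needy atoms
  cand <- arom_bonds[needy[bonds$a[arom_bonds]] & needy[bonds$b[arom_bonds]]]
  adj <- lapply(seq_len(nA), function(a) integer())
  for (k in cand) {
    adj[[bonds$a[k]]] <- c(adj[[bonds$a[k]]], k)
    adj[[bonds$b[k]]] <- c(adj[[bonds$b[k]]], k)
  }
  matched <- integer(0)
  done <- logical(nA)
  match_rec <- function(todo) {
    while (length(todo) && done[todo[1]]) todo <- todo[-1]
    if (length(todo) == 0L) return(TRUE)
    v <- todo[1]
    for (k in adj[[v]]) {
      u <- if (bonds$a[k] == v) bonds$b[k] else bonds$a[k]
      if (done[u]) next
      done[v] <<- TRUE; done[u] <<- TRUE
      matched <<- c(matched, k)
      if (match_rec(todo[-1])) return(TRUE)
      done[v] <<- FALSE; done[u] <<- FALSE
      matched <<- matched[-length(matched)]
    }
    FALSE
  }
  if (!match_rec(need_idx))
    smilesError("cannot kekulize aromatic system (no alternating bond assignment)",
      atpos[need_idx[1]])
  bonds$order[matched] <- "double"
  bonds$order[setdiff(arom_bonds, matched)] <- "single"
  list(bonds = bonds)
}

# default implicit-H count an organic-subset bare atom would get for a
# given bond-order sum, or NA if no standard valence fits
.defaultH <- function(element, bsum) {
  vals <- .valences[[element]]
  if (is.null(vals)) return(NA_integer_)
  fit <- vals[vals >= bsum]
  if (length(fit) == 0L) return(NA_integer_)
  fit[1] - bsum
}

#' Write a molecular graph as SMILES
#'
#' Deterministic emission: depth-first from atom 1 (and from the
#' lowest-index atom of each further disconnected component, joined by
#' dots), visiting neighbors in ascending index order. Output is always
#' Kekule (no aromatic lowercase atoms). Atoms are written bare when they
#' belong to the SMILES organic subset, carry no charge, and their stored
#' hydrogen count equals the default-valence count; otherwise in brackets
#' with explicit H count and charge.
#'
#' Re-parsing the output yields a graph isomorphic to the input (same
#' multiset of atoms with hydrogens/charges and same bond multiset).
#'
#' @param g a non-empty [MolecularGraph-class]
#' @return single SMILES string
#' @export
writeSmiles <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  n <- numAtoms(g)
  if (n == 0L) stop("cannot write SMILES for an empty molecular graph")
  bonds <- g@bonds
  adj <- lapply(seq_len(n), function(a) integer())
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a[k]]] <- c(adj[[bonds$a[k]]], k)
    adj[[bonds$b[k]]] <- c(adj[[bonds$b[k]]], k)
  }
  other <- function(k, v) if (bonds$a[k] == v) bonds$b[k] else bonds$a[k]
  bondSym <- function(ord) switch(ord, single = "", double = "=", triple = "#")
  bsum <- integer(n)
  ordnum <- c(single = 1L, double = 2L, triple = 3L)
  for (k in seq_len(nrow(bonds))) {
    o <- ordnum[[bonds$order[k]]]
    bsum[bonds$a[k]] <- bsum[bonds$a[k]] + o
    bsum[bonds$b[k]] <- bsum[bonds$b[k]] + o
  }
  atomToken <- function(v) {
    el <- g@atoms$element[v]; ch <- g@atoms$charge[v]; h <- g@atoms$hcount[v]
    if (el %in% ORGANIC_SUBSET && ch == 0L &&
        identical(.defaultH(el, bsum[v]), h))
      return(el)
    htok <- if (h == 1L) "H" else if (h > 1L) paste0("H", h) else ""
    ctok <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-" else
      sprintf("%+d", ch)
    paste0("[", el, htok, ctok, "]")
  }
  visited <- logical(n)
  # per-component DFS: classify tree vs ring (back) edges
  out <- character(0)
  ring_num_of <- new.env(parent = emptyenv())  # bond k -> assigned number
  for (root in seq_len(n)) {
    if (visited[root]) next
    # spanning tree by depth-first search, neighbors in ascending index
    # order; bonds off the tree become ring closures
    parent_edge <- rep(NA_integer_, n)
    seen <- logical(n)
    ring_edges <- integer(0)
    edge_seen <- logical(nrow(bonds))
    children <- lapply(seq_len(n), function(a) integer())
    dfs <- function(v) {
      ks <- adj[[v]]
      if (length(ks) == 0L) return(invisible())
      us <- vapply(ks, other, 0L, v = v)
      for (idx in order(us)) {
        k <- ks[idx]; u <- us[idx]
        if (edge_seen[k]) next
        edge_seen[k] <<- TRUE
        if (!seen[u]) {
          seen[u] <<- TRUE
          parent_edge[u] <<- k
          children[[v]] <<- c(children[[v]], u)
          dfs(u)
        } else {
          ring_edges <<- c(ring_edges, k)
        }
      }
    }
    seen[root] <- TRUE
    dfs(root)
    comp <- which(seen)
    # ring-closure numbering: assign while emitting
    free_nums <- 1:99
    open_num <- integer(0)        # bond k -> number
    names(open_num) <- character(0)
    ringTok <- function(num) if (num <= 9L) as.character(num) else sprintf("%%%02d", num)
    emit <- function(v) {
      tok <- atomToken(v)
      # ring closures incident to v, ordered by partner index
      rks <- ring_edges[bonds$a[ring_edges] == v | bonds$b[ring_edges] == v]
      if (length(rks)) rks <- rks[order(vapply(rks, other, 0L, v = v))]
      for (k in rks) {
        key <- as.character(k)
        if (is.na(match(key, names(open_num)))) {
          num <- free_nums[1]; free_nums <<- free_nums[-1]
          open_num[key] <<- num
          tok <- paste0(tok, bondSym(bonds$order[k]), ringTok(num))
        } else {
          num <- open_num[[key]]
          open_num <<- open_num[names(open_num) != key]
          free_nums <<- sort(c(free_nums, num))
          tok <- paste0(tok, ringTok(num))
        }
      }
      kids <- children[[v]]
      if (length(kids)) {
        for (idx in seq_along(kids)) {
          u <- kids[idx]
          sub <- paste0(bondSym(bonds$order[parent_edge[u]]), emit(u))
          tok <- if (idx < length(kids)) paste0(tok, "(", sub, ")")
            else paste0(tok, sub)
        }
      }
      tok
    }
    out <- c(out, emit(root))
    visited[comp] <- TRUE
  }
  paste(out, collapse = ".")
}

#' Address one atom of a molecular graph
#'
#' Atoms are addressed by their 1-based position in the graph's stored atom
#' order together with the expected element symbol; the element acts as a
#' semantic guard (a mismatch is the error semantic validation reports for
#' an atom reference that does not fit its residue).
#'
#' @param g a [MolecularGraph-class]
#' @param element expected element symbol
#' @param index 1-based atom index
#' @return one-row data.frame (element, charge, hcount) plus the index
#' @export
atomAt <- function(g, element, index) {
  stopifnot(is(g, "MolecularGraph"))
  n <- numAtoms(g)
  if (!is.numeric(index) || length(index) != 1L || is.na(index) ||
      index < 1L || index > n)
    stop(errorCondition(
      sprintf("atom index %s out of range 1..%d", as.character(index), n),
      class = c("mf_atom_error", "mf_error")))
  found <- g@atoms$element[index]
  if (!identical(found, element))
    stop(errorCondition(
      sprintf("element mismatch at atom %d: expected %s, found %s",
        as.integer(index), element, found),
      class = c("mf_atom_error", "mf_error")))
  cbind(g@atoms[index, , drop = FALSE], index = as.integer(index))
}

#' Test whether two molecular graphs are isomorphic
#'
#' Backtracking search for a bijection of atoms preserving element, formal
#' charge, hydrogen count, and the bond multiset with orders. Used by the
#' round-trip contract of [writeSmiles()] and to match inline-defined
#' residues against alphabet residues.
#'
#' @param g1,g2 two [MolecularGraph-class] objects
#' @return logical
#' @export
graphIsomorphic <- function(g1, g2) {
  n <- numAtoms(g1)
  if (n != numAtoms(g2) || nrow(g1@bonds) != nrow(g2@bonds)) return(FALSE)
  if (n == 0L) return(TRUE)
  sig <- function(g) {
    deg <- integer(numAtoms(g)); nbel <- vector("list", numAtoms(g))
    for (k in seq_len(nrow(g@bonds))) {
      a <- g@bonds$a[k]; b <- g@bonds$b[k]; o <- g@bonds$order[k]
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      nbel[[a]] <- c(nbel[[a]], paste0(g@atoms$element[b], o))
      nbel[[b]] <- c(nbel[[b]], paste0(g@atoms$element[a], o))
    }
    vapply(seq_len(numAtoms(g)), function(a) paste(
      g@atoms$element[a], g@atoms$charge[a], g@atoms$hcount[a], deg[a],
      paste(sort(nbel[[a]]), collapse = ","), sep = "|"), "")
  }
  s1 <- sig(g1); s2 <- sig(g2)
  if (!identical(sort(s1), sort(s2))) return(FALSE)
  bondKey <- function(g, a, b) {
    kk <- which((g@bonds$a == min(a, b)) & (g@bonds$b == max(a, b)))
    if (length(kk) == 0L) NA_character_ else g@bonds$order[kk]
  }
  adj1 <- lapply(seq_len(n), function(a) integer())
  for (k in seq_len(nrow(g1@bonds))) {
    adj1[[g1@bonds$a[k]]] <- c(adj1[[g1@bonds$a[k]]], g1@bonds$b[k])
    adj1[[g1@bonds$b[k]]] <- c(adj1[[g1@bonds$b[k]]], g1@bonds$a[k])
  }
  # visit g1 atoms connectivity-first
  ordv <- integer(0); seen <- logical(n)
  for (root in seq_len(n)) {
    if (seen[root]) next
    stk <- root; seen[root] <- TRUE
    while (length(stk)) {
      v <- stk[length(stk)]; stk <- stk[-length(stk)]
      ordv <- c(ordv, v)
      for (u in adj1[[v]]) if (!seen[u]) { seen[u] <- TRUE; stk <- c(stk, u) }
    }
  }
  map <- rep(NA_integer_, n)
  used <- logical(n)
  assign_rec <- function(pos) {
    if (pos > n) {
      # verify full bond correspondence
      for (k in seq_len(nrow(g1@bonds))) {
        if (!identical(bondKey(g2, map[g1@bonds$a[k]], map[g1@bonds$b[k]]),
            g1@bonds$order[k])) return(FALSE)
      }
      return(TRUE)
    }
    v <- ordv[pos]
    for (w in which(s2 == s1[v] & !used)) {
      ok <- TRUE
      for (u in adj1[[v]]) {
        if (!is.na(map[u]) &&
            !identical(bondKey(g2, w, map[u]), bondKey(g1, v, u))) { ok <- FALSE; break }
      }
      if (!ok) next
      map[v] <<- w; used[w] <<- TRUE
      if (assign_rec(pos + 1L)) return(TRUE)
      map[v] <<- NA_integer_; used[w] <<- FALSE
    }
    FALSE
  }
  assign_rec(1L)
}

#' @describeIn getFormula element counts of a molecular graph, including
#'   implicit hydrogens
#' @export
setMethod("getFormula", "MolecularGraph", function(x, ...) {
  if (numAtoms(x) == 0L) return(integer(0))
  f <- integer()
  tab <- table(x@atoms$element)
  f[names(tab)] <- as.integer(tab)
  h <- sum(x@atoms$hcount)
  if (h > 0L) f["H"] <- (if ("H" %in% names(f)) f[["H"]] else 0L) + h
  f[f != 0L]
})

#' @describeIn getMolWeight molecular weight of a molecular graph
#' @export
setMethod("getMolWeight", "MolecularGraph", function(x, ...) {
  if (numAtoms(x) == 0L) stop("molecular weight of an empty graph is undefined")
  formulaWeight(getFormula(x))
})

#' @describeIn getCharge net formal charge of a molecular graph
#' @export
setMethod("getCharge", "MolecularGraph", function(x, ...) {
  as.integer(sum(x@atoms$charge))
})

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d atoms, %d bonds", numAtoms(object),
    nrow(object@bonds)))
  if (numAtoms(object) > 0L)
    cat(sprintf(" | %s | charge %+d", formulaString(getFormula(object)),
      getCharge(object)))
  cat("\n")
})
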