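# Seeded corpus generator: random polymer descriptions that are valid by
# construction, or that carry one labeled defect (a syntax defect, or a
# semantic defect drawn from rules V1-V9). The generator is the test
# surface for the grammar and the validator; given a seed its output is
# fixed exactly.

#' @rdname generateCorpus
#' @param nRecords number of records
#' @param alphabet alphabet id (`"protein"`, `"dna"`, `"rna"`); semantic
#'   error injection requires `"protein"` (the packaged crosslink ontology
#'   is protein chemistry)
#' @param lengthRange integer c(min, max) residues per record
#' @param pModified probability that a position carries a modified residue
#' @param pNick,pCrosslink,pCircular per-record feature probabilities
#' @param seed integer; fixes the output exactly
#' @param errorMode `"none"`, `"syntax"`, or `"semantic"`
#' @export
corpusSpec <- function(nRecords, alphabet = "protein",
    lengthRange = c(5L, 15L), pModified = 0.2, pNick = 0.2,
    pCrosslink = 0.2, pCircular = 0.1, seed = 1L,
    errorMode = c("none", "syntax", "semantic")) {
  new("CorpusSpec", nRecords = as.integer(nRecords), alphabet = alphabet,
    lengthRange = as.integer(lengthRange), pModified = pModified,
    pNick = pNick, pCrosslink = pCrosslink, pCircular = pCircular,
    seed = as.integer(seed), errorMode = match.arg(errorMode))
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

# residue codes usable in a chain interior, split canonical vs modified
.corpusCodes <- function(al) {
  codes <- names(al@residues)
  caps <- vapply(al@residues, function(r) isLeftCap(r) || isRightCap(r), TRUE)
  usable <- codes[!caps]
  list(
    canonical = usable[nchar(usable) == 1L],
    modified = usable[nchar(usable) > 1L])
}

# one syntactically and semantically valid polymer description
.randomCleanText <- function(al, spec) {
  cc <- .corpusCodes(al)
  L <- sample(spec@lengthRange[1]:spec@lengthRange[2], 1L)
  codes <- cc$canonical[sample.int(length(cc$canonical), L, replace = TRUE)]
  mod <- stats::runif(L) < spec@pModified
  codes[mod] <- cc$modified[sample.int(length(cc$modified), sum(mod),
    replace = TRUE)]
  attrs <- character()
  crosslinked <- FALSE
  linkpos <- integer()
  if (al@type == "protein" && L >= 4L && stats::runif(1) < spec@pCrosslink) {
    ij <- sort(sample.int(L, 2L))
    codes[ij] <- "C"
    attrs <- c(attrs, sprintf("x-link: [type: disulfide | l: %d | r: %d]",
      ij[1], ij[2]))
    crosslinked <- TRUE
    linkpos <- ij
  }
  tokens <- ifelse(nchar(codes) == 1L, codes, paste0("{", codes, "}"))
  # occasionally exercise inline definitions (a glycine spelled out);
  # never on a position anchoring a crosslink
  free <- setdiff(seq_len(L), linkpos)
  if (length(free) && stats::runif(1) < 0.15) {
    i <- sample1(free)
    rng <- sort(sample.int(L, 2L))
    rng[1] <- min(rng[1], i); rng[2] <- max(rng[2], i)
    tokens[i] <- paste0("[id: gx | structure: \"OC(=O)CN\"",
      " | l-bond-atom: N5 | l-displaced-atom: H5",
      " | r-bond-atom: C2 | r-displaced-atom: O1 | r-displaced-atom: H1",
      " | base-monomer: G",
      sprintf(" | position: %d-%d]", rng[1], rng[2]))
  }
  circular <- stats::runif(1) < spec@pCircular && L >= 2L
  if (!crosslinked && stats::runif(1) < spec@pNick && L >= 2L) {
    i <- sample.int(L - 1L, 1L)
    tokens[i] <- paste0(tokens[i], ":")
  }
  if (circular) attrs <- c(attrs, "circular")
  if (stats::runif(1) < 0.1)
    attrs <- c(attrs, sprintf("extra: [mass: %.2f | charge: %d]",
      stats::runif(1, 1, 100), sample(-3:3, 1L)))
  if (stats::runif(1) < 0.1) attrs <- c(attrs, "comments: \"generated record\"")
  paste(c(paste(tokens, collapse = ""), attrs), collapse = " | ")
}

# inject one semantic defect of the given rule into a fresh clean backbone
.injectSemantic <- function(rule, al, spec) {
  cc <- .corpusCodes(al)
  L <- max(4L, sample(spec@lengthRange[1]:spec@lengthRange[2], 1L))
  codes <- cc$canonical[sample.int(length(cc$canonical), L, replace = TRUE)]
  tokens <- ifelse(nchar(codes) == 1L, codes, paste0("{", codes, "}"))
  attrs <- character()
  interior <- function() sample(2:(L - 1L), 1L)
  pickTwo <- function() sort(sample.int(L, 2L))
  switch(rule,
    V1 = {  # a residue with no right bond atoms in the chain interior
      i <- interior()
      tokens[i] <- paste0("[id: stub | structure: \"OC(=O)CN\"",
        " | l-bond-atom: N5 | l-displaced-atom: H5]")
    },
    V2 = {  # a left cap (amino-terminal acetyl) misplaced mid-chain
      tokens[interior()] <- "{ACE}"
    },
    V3 = {  # circular polymer whose first residue cannot close the ring
      tokens[1] <- "{ACE}"
      attrs <- c(attrs, "circular")
    },
    V4 = {  # crosslink bond atom with mismatched element
      ij <- pickTwo(); codes[ij] <- "C"
      tokens[ij] <- "C"
      attrs <- c(attrs, sprintf(
        "x-link: [l-bond-atom: %dS2 | r-bond-atom: %dS7]", ij[1], ij[2]))
    },
    V5 = {  # displacing a hydrogen from an atom that has none
      ij <- pickTwo(); codes[ij] <- "C"
      tokens[ij] <- "C"
      attrs <- c(attrs, sprintf(
        "x-link: [l-bond-atom: %dS7 | r-bond-atom: %dS7 | l-displaced-atom: %dH2]",
        ij[1], ij[2], ij[1]))
    },
    V6 = {  # crosslink coordinate beyond the sequence length
      i <- sample.int(L, 1L); codes[i] <- "C"; tokens[i] <- "C"
      attrs <- c(attrs, sprintf(
        "x-link: [type: disulfide | l: %d | r: %d]", i, L + sample(1:9, 1L)))
    },
    V7 = {  # disulfide anchored on a residue without a thiol
      ij <- pickTwo()
      codes[ij[1]] <- "A"; tokens[ij[1]] <- "A"
      codes[ij[2]] <- "C"; tokens[ij[2]] <- "C"
      attrs <- c(attrs, sprintf(
        "x-link: [type: disulfide | l: %d | r: %d]", ij[1], ij[2]))
    },
    V8 = {  # one cysteine sulfur consumed by two crosslinks
      ijk <- sort(sample.int(L, 3L))
      codes[ijk] <- "C"; tokens[ijk] <- "C"
      attrs <- c(attrs,
        sprintf("x-link: [type: disulfide | l: %d | r: %d]", ijk[1], ijk[2]),
        sprintf("x-link: [type: disulfide | l: %d | r: %d]", ijk[1], ijk[3]))
    },
    V9 = {  # uncertainty range beyond the sequence
      i <- interior()
      tokens[i] <- paste0("[id: gx | structure: \"OC(=O)CN\"",
        " | l-bond-atom: N5 | l-displaced-atom: H5",
        " | r-bond-atom: C2 | r-displaced-atom: O1 | r-displaced-atom: H1",
        sprintf(" | position: %d-%d]", i, L + sample(1:9, 1L)))
    },
    stop("unknown semantic rule ", rule)
  )
  paste(c(paste(tokens, collapse = ""), attrs), collapse = " | ")
}

.injectSyntax <- function(al, spec) {
  base <- .randomCleanText(al, spec)
  defect <- sample.int(6L, 1L)
  switch(defect,
    paste0(base, "{"),                                  # unclosed brace
    paste0("[id: broken | structure: \"CC", base),      # unclosed bracket
    sub("^(.)", "\\1!", base),                          # stray character
    paste0(base, " | x-link: [type: disulfide | l: 1 | r: 1]"),  # self-link
    paste0(base, " | comments: \"unterminated"),        # open quote
    paste0(base, " | bogus-attribute"))                 # unknown attribute
}

#' Generate a seeded corpus of polymer descriptions
#'
#' With `errorMode = "none"` every record parses and validates cleanly by
#' construction. With `"syntax"` each record carries one grammar defect
#' and is labeled `"syntax"`. With `"semantic"` each record carries one
#' defect of a validation rule, assigned round-robin over V1-V9 so every
#' rule is covered evenly, and is labeled with that rule id. The same
#' spec always produces the identical corpus.
#'
#' @param spec a [CorpusSpec-class] from [corpusSpec()]
#' @return data.frame with columns `text` and `expected` (`"valid"`, a
#'   rule id, or `"syntax"`)
#' @examples
#' generateCorpus(corpusSpec(3, seed = 42))$expected
#' @export
generateCorpus <- function(spec) {
  stopifnot(is(spec, "CorpusSpec"))
  al <- builtinAlphabet(spec@alphabet)
  if (spec@errorMode == "semantic" && al@type != "protein")
    stop("semantic error injection requires the protein alphabet")
  withSeed(spec@seed, {
    rules <- paste0("V", 1:9)
    recs <- lapply(seq_len(spec@nRecords), function(i) {
      switch(spec@errorMode,
        none = data.frame(text = .randomCleanText(al, spec),
          expected = "valid", stringsAsFactors = FALSE),
        syntax = data.frame(text = .injectSyntax(al, spec),
          expected = "syntax", stringsAsFactors = FALSE),
        semantic = {
          rule <- rules[(i - 1L) %% 9L + 1L]
          data.frame(text = .injectSemantic(rule, al, spec),
            expected = rule, stringsAsFactors = FALSE)
        })
    })
    do.call(rbind, recs)
  })
}

#' Generate random complexes with their subunit structures
#'
#' Companion generator for the complex grammar: each record pairs a
#' complex description with the polymer structures of its subunits.
#' Crosslinks are disulfides between cysteines of different subunit
#' copies; a fraction use explicit atom references instead of the
#' ontology type. All records validate cleanly.
#'
#' @param n number of records
#' @param seed integer seed
#' @return list of `list(text =, subunits =)` records
#' @export
generateComplexCorpus <- function(n, seed = 1L) {
  al <- builtinAlphabet("protein")
  cc <- .corpusCodes(al)
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      nsub <- sample(1:3, 1L)
      ids <- paste0("su", seq_len(nsub))
      subunits <- list()
      terms <- character(nsub)
      for (k in seq_len(nsub)) {
        L <- sample(4:8, 1L)
        codes <- cc$canonical[sample.int(length(cc$canonical), L,
          replace = TRUE)]
        codes[sample.int(L, 1L)] <- "C"   # crosslink anchor always available
        subunits[[ids[k]]] <- polymer(codes, al)
        st <- if (nsub == 1L) sample(2:3, 1L) else sample(1:3, 1L)
        terms[k] <- sprintf("%d * %s", st, ids[k])
      }
      text <- paste(terms, collapse = " + ")
      stoich <- as.integer(sub(" \\*.*$", "", terms))
      if (stats::runif(1) < 0.6) {
        k1 <- sample.int(nsub, 1L)
        k2 <- if (nsub > 1L && stats::runif(1) < 0.5) sample(setdiff(
          seq_len(nsub), k1), 1L) else k1
        c1 <- sample.int(stoich[k1], 1L)
        c2 <- sample.int(stoich[k2], 1L)
        if (k1 == k2 && c1 == c2) {
          if (stoich[k1] > 1L) {
            c2 <- if (c1 == 1L) 2L else c1 - 1L
          } else {
            k2 <- NA
          }
        }
        if (!is.na(k2)) {
          posOf <- function(k) which(vapply(
            subunits[[ids[k]]]@occurrences, `[[`, "", "code") == "C")[1]
          p1 <- posOf(k1); p2 <- posOf(k2)
          if (stats::runif(1) < 0.3) {
            text <- paste0(text, sprintf(
              " | x-link: [l-bond-atom: %s(%d)-%dS7 | l-displaced-atom: %s(%d)-%dH7 | r-bond-atom: %s(%d)-%dS7 | r-displaced-atom: %s(%d)-%dH7]",
              ids[k1], c1, p1, ids[k1], c1, p1, ids[k2], c2, p2, ids[k2], c2, p2))
          } else {
            text <- paste0(text, sprintf(
              " | x-link: [type: disulfide | l: %s(%d)-%d | r: %s(%d)-%d]",
              ids[k1], c1, p1, ids[k2], c2, p2))
          }
        }
      }
      list(text = text, subunits = subunits)
    })
  })
}
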