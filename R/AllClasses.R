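#' @import methods
NULL

#' Molecular graph
#'
#' The concrete chemistry layer: atoms (element, formal charge, implicit
#' hydrogen count) and bonds (order). Atoms are stored in order of first
#' appearance in the SMILES string the graph was parsed from; that order is
#' the coordinate system used to address individual atoms of a residue
#' (see [atomAt()]).
#'
#' @slot atoms data.frame with columns `element` (character), `charge`
#'   (integer, elementary charges), `hcount` (integer, implicit hydrogens).
#'   Row i is the atom with index i.
#' @slot bonds data.frame with columns `a`, `b` (integer atom indices,
#'   `a < b`) and `order` (one of `"single"`, `"double"`, `"triple"`).
#' @aliases MolecularGraph
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(atoms = "data.frame", bonds = "data.frame"))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msg <- character()
  if (!all(c("element", "charge", "hcount") %in% names(a)))
    msg <- c(msg, "atoms must have columns element, charge, hcount")
  if (!all(c("a", "b", "order") %in% names(b)))
    msg <- c(msg, "bonds must have columns a, b, order")
  if (length(msg) == 0L && nrow(a) > 0L) {
    if (any(a$hcount < 0L)) msg <- c(msg, "implicit hydrogen counts must be non-negative")
    wt <- elementWeights()
    unknown <- setdiff(unique(a$element), names(wt))
    if (length(unknown))
      msg <- c(msg, paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(msg) == 0L && nrow(b) > 0L) {
    if (any(b$a < 1L | b$b < 1L | b$a > nrow(a) | b$b > nrow(a)))
      msg <- c(msg, "bond endpoints out of range")
    if (any(b$a == b$b)) msg <- c(msg, "self-bonds are not allowed")
    key <- paste(pmin(b$a, b$b), pmax(b$a, b$b))
    if (anyDuplicated(key)) msg <- c(msg, "at most one bond per atom pair")
    if (!all(b$order %in% c("single", "double", "triple")))
      msg <- c(msg, "bond order must be single, double, or triple")
  }
  if (length(msg)) msg else TRUE
})

#' Residue: a monomer or cap of a polymer alphabet
#'
#' A residue couples a molecular structure with the atoms through which it
#' bonds to the preceding (left) and following (right) residue of a chain,
#' and the atoms displaced when those bonds form (e.g. the water lost in
#' peptide-bond formation). A residue with no left bond atoms is a left cap
#' (it can only start a chain, like a 5' cap or an amino-terminal acetyl
#' group); one with no right bond atoms is a right cap.
#'
#' Atom references (`lBondAtoms` etc.) are lists of atom specs: each a list
#' with `element`, `index` (1-based position in the structure's atom order;
#' for element `"H"` the index names the heavy atom bearing the implicit
#' hydrogen) and `chargeDelta` (formal-charge change applied when the bond
#' forms).
#'
#' @slot code short residue code (single letter, or a longer code written
#'   in braces in the polymer grammar)
#' @slot id stable identifier
#' @slot name human-readable name
#' @slot structure [MolecularGraph-class] of the free residue
#' @slot lBondAtoms,rBondAtoms lists of atom specs bonding left/right
#' @slot lDisplacedAtoms,rDisplacedAtoms lists of atom specs displaced when
#'   the left/right bond forms
#' @slot baseMonomers character vector of canonical residue codes this
#'   residue derives from (empty for residues of unknown origin)
#' @slot aliases alternative codes resolving to this residue
#' @slot xrefs list of `list(database=, accession=)` cross-references
#' @slot comments free text
#' @exportClass Residue
setClass("Residue",
  representation(code = "character", id = "character", name = "character",
    structure = "MolecularGraph",
    lBondAtoms = "list", rBondAtoms = "list",
    lDisplacedAtoms = "list", rDisplacedAtoms = "list",
    baseMonomers = "character", aliases = "character",
    xrefs = "list", comments = "character"))

#' Alphabet of residues
#'
#' A registry mapping residue codes to molecular definitions for one
#' polymer chemistry (DNA, RNA, or protein). Codes are case-sensitive;
#' single-character codes are letters usable directly in the polymer
#' grammar, longer codes are written in braces.
#'
#' @slot id alphabet identifier
#' @slot name human-readable name
#' @slot type one of `"DNA"`, `"RNA"`, `"protein"`
#' @slot residues named list of [Residue-class], keyed by code
#' @exportClass Alphabet
setClass("Alphabet",
  representation(id = "character", name = "character", type = "character",
    residues = "list"))

setValidity("Alphabet", function(object) {
  msg <- character()
  if (!object@type %in% c("DNA", "RNA", "protein"))
    msg <- c(msg, "type must be DNA, RNA, or protein")
  codes <- names(object@residues)
  if (anyDuplicated(codes)) msg <- c(msg, "residue codes must be unique")
  one <- codes[nchar(codes) == 1L]
  if (length(one) && !all(grepl("^[A-Za-z]$", one)))
    msg <- c(msg, "single-character codes must be letters")
  for (r in object@residues) {
    bad <- setdiff(r@baseMonomers, codes)
    if (length(bad))
      msg <- c(msg, paste0("residue ", r@code, ": unresolved base monomer(s) ",
        paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Crosslink type
#'
#' An entry of the crosslink ontology: the atoms of the left and right
#' residue that form the covalent bond(s) of the crosslink, the atoms
#' displaced by bond formation, and (optionally) the residue codes allowed
#' in each slot. The atom specs are interpreted relative to the structure
#' of the residue occupying the corresponding slot.
#'
#' @slot id identifier, e.g. `"disulfide"`
#' @slot name human-readable name
#' @slot lBondAtoms,rBondAtoms,lDisplacedAtoms,rDisplacedAtoms atom-spec lists
#' @slot allowedL,allowedR residue codes allowed in each slot (empty = any)
#' @exportClass CrosslinkType
setClass("CrosslinkType",
  representation(id = "character", name = "character",
    lBondAtoms = "list", rBondAtoms = "list",
    lDisplacedAtoms = "list", rDisplacedAtoms = "list",
    allowedL = "character", allowedR = "character"))

#' Ontology of crosslinks
#'
#' @slot types named list of [CrosslinkType-class], keyed by id.
#' @exportClass CrosslinkOntology
setClass("CrosslinkOntology", representation(types = "list"))

setValidity("CrosslinkOntology", function(object) {
  if (anyDuplicated(names(object@types))) "crosslink ids must be unique" else TRUE
})

#' Polymer: a chain of residues with nicks, crosslinks, and circularity
#'
#' The mid-level representation of a DNA, RNA, or protein molecule: an
#' ordered sequence of residue occurrences, a set of nick positions (a nick
#' at i means there is no backbone bond between residues i and i+1), a list
#' of intra-chain crosslinks, a circularity flag, and optional metadata for
#' observed-but-unexplained extra mass/charge.
#'
#' Each element of `occurrences` is a list with fields `residue`
#' ([Residue-class]), `code` (as written), `inline` (logical; TRUE when the
#' residue was defined inline in the description rather than drawn from the
#' alphabet), `range` (NULL or `c(lo, hi)` position-uncertainty bounds) and
#' `comments`.
#'
#' Each element of `crosslinks` is a list with either `type` (an ontology
#' id) plus `l`, `r` residue positions, or `type = NA` plus explicit
#' `lBondAtoms`/`rBondAtoms`/`lDisplacedAtoms`/`rDisplacedAtoms`, where
#' every entry is `list(pos = <residue position>, spec = <atom spec>)`.
#'
#' @slot alphabet [Alphabet-class]
#' @slot occurrences list of residue occurrences (see Details)
#' @slot nicks integer vector of nick positions
#' @slot crosslinks list of intra-chain crosslinks (see Details)
#' @slot circular logical
#' @slot extraMass numeric, additional observed mass in daltons (NA if none)
#' @slot extraCharge integer, additional observed charge (NA if none)
#' @slot comments free text
#' @exportClass Polymer
setClass("Polymer",
  representation(alphabet = "Alphabet", occurrences = "list",
    nicks = "integer", crosslinks = "list", circular = "logical",
    extraMass = "numeric", extraCharge = "integer", comments = "character"))

setValidity("Polymer", function(object) {
  msg <- character()
  n <- length(object@occurrences)
  if (n == 0L) msg <- c(msg, "a polymer must contain at least one residue")
  if (isTRUE(object@circular) && n < 2L)
    msg <- c(msg, "a circular polymer must contain at least two residues")
  nk <- object@nicks
  if (length(nk)) {
    lim <- if (isTRUE(object@circular)) n else n - 1L
    if (any(nk < 1L | nk > lim))
      msg <- c(msg, sprintf("nick positions must lie in 1..%d", lim))
    if (anyDuplicated(nk)) msg <- c(msg, "duplicate nick positions")
  }
  if (length(msg)) msg else TRUE
})

#' Complex: subunits with stoichiometry plus inter-subunit crosslinks
#'
#' Each element of `subunits` is a list with `id`, `stoichiometry`
#' (positive integer) and `structure` (a [Polymer-class], a
#' [MolecularGraph-class] for a small-molecule subunit, or NULL when only
#' the id is known). Crosslink slots address residues hierarchically as
#' `list(subunit = id, copy = integer, pos = residue position)`; explicit
#' atom entries additionally carry `spec`.
#'
#' @slot subunits list of subunits (see Details)
#' @slot crosslinks list of inter-subunit crosslinks; same shape as for
#'   [Polymer-class] but with hierarchical slots
#' @exportClass ComplexForm
setClass("ComplexForm",
  representation(subunits = "list", crosslinks = "list"))

setValidity("ComplexForm", function(object) {
  msg <- character()
  ids <- vapply(object@subunits, `[[`, "", "id")
  if (anyDuplicated(ids)) msg <- c(msg, "subunit ids must be unique")
  st <- vapply(object@subunits, `[[`, 0, "stoichiometry")
  if (any(st < 1)) msg <- c(msg, "stoichiometries must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Validation report
#'
#' Findings of semantic validation. A molecule assembles successfully if
#' and only if the report has no errors. Rule ids identify the semantic
#' rule violated (see [validatePolymer()]).
#'
#' @slot findings data.frame with columns `severity` ("error"/"warning"),
#'   `rule`, `location`, `message`
#' @exportClass ValidationReport
setClass("ValidationReport", representation(findings = "data.frame"))

#' Corpus generation settings
#'
#' Settings for the seeded random polymer corpus generator used to exercise
#' the grammar and the semantic validator (see [generateCorpus()]).
#'
#' @slot nRecords number of records
#' @slot alphabet alphabet id ("dna", "rna", "protein")
#' @slot lengthRange integer c(min, max) sequence length
#' @slot pModified,pNick,pCrosslink,pCircular per-record probabilities
#' @slot seed integer seed; fixes the output exactly
#' @slot errorMode "none", "syntax", or "semantic"
#' @exportClass CorpusSpec
setClass("CorpusSpec",
  representation(nRecords = "integer", alphabet = "character",
    lengthRange = "integer", pModified = "numeric", pNick = "numeric",
    pCrosslink = "numeric", pCircular = "numeric", seed = "integer",
    errorMode = "character"))

setValidity("CorpusSpec", function(object) {
  msg <- character()
  p <- c(object@pModified, object@pNick, object@pCrosslink, object@pCircular)
  if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (!object@errorMode %in% c("none", "syntax", "semantic"))
    msg <- c(msg, "errorMode must be none, syntax, or semantic")
  if (length(object@lengthRange) != 2L || object@lengthRange[1] < 1L ||
      object@lengthRange[2] < object@lengthRange[1])
    msg <- c(msg, "lengthRange must be c(min, max) with 1 <= min <= max")
  if (length(msg)) msg else TRUE
})
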