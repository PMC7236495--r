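# Alphabets of residues/caps and the crosslink ontology: data model, YAML
# I/O, and the packaged fixture alphabets (DNA, RNA, protein).

#' Atom spec: reference to one atom of a residue structure
#'
#' @param element element symbol; `"H"` refers to an implicit hydrogen on
#'   the heavy atom named by `index`
#' @param index 1-based atom index in the residue structure's atom order
#' @param chargeDelta formal-charge change applied to the referenced atom
#'   when the bond forms
#' @return atom-spec list
#' @export
atomSpec <- function(element, index, chargeDelta = 0L) {
  stopifnot(is.character(element), length(element) == 1L, index >= 1L)
  list(element = element, index = as.integer(index),
    chargeDelta = as.integer(chargeDelta))
}

#' @rdname atomSpec
#' @param s compact text form, e.g. `"C2"`, `"H1"`, `"O3-1"`, `"N7+1"`
#' @export
parseAtomSpec <- function(s) {
  m <- regmatches(s, regexec("^([A-Z][a-z]?)([0-9]+)([+-][0-9]+)?$", s))[[1]]
  if (length(m) == 0L)
    stop(errorCondition(paste0("malformed atom reference '", s, "'"),
      class = c("mf_atomspec_error", "mf_error")))
  atomSpec(m[2], as.integer(m[3]), if (nzchar(m[4])) as.integer(m[4]) else 0L)
}

#' @rdname atomSpec
#' @param spec an atom-spec list
#' @export
formatAtomSpec <- function(spec) {
  paste0(spec$element, spec$index,
    if (spec$chargeDelta != 0L) sprintf("%+d", spec$chargeDelta) else "")
}

# Resolve an atom spec against a structure. For heavy atoms the element
# must match the atom at the index (atomAt's semantic guard); for "H" the
# index must name a valid heavy atom. Returns invisible(TRUE) or raises.
resolveAtomSpec <- function(g, spec) {
  if (spec$element == "H") {
    n <- numAtoms(g)
    if (spec$index < 1L || spec$index > n)
      stop(errorCondition(
        sprintf("hydrogen reference H%d: heavy-atom index out of range 1..%d",
          spec$index, n),
        class = c("mf_atom_error", "mf_error")))
  } else {
    atomAt(g, spec$element, spec$index)
  }
  invisible(TRUE)
}

#' Construct a residue
#'
#' @param code residue code
#' @param structure SMILES string or [MolecularGraph-class]
#' @param id,name identifier and human-readable name
#' @param lBondAtoms,rBondAtoms,lDisplacedAtoms,rDisplacedAtoms lists of
#'   atom specs (or character vectors in compact text form)
#' @param baseMonomers canonical residue codes this residue derives from
#' @param aliases alternative codes
#' @param xrefs character vector of `"database:accession"` cross-references
#' @param comments free text
#' @return a [Residue-class]
#' @export
residue <- function(code, structure, id = code, name = code,
    lBondAtoms = list(), rBondAtoms = list(),
    lDisplacedAtoms = list(), rDisplacedAtoms = list(),
    baseMonomers = character(), aliases = character(),
    xrefs = character(), comments = character()) {
  if (is.character(structure)) structure <- parseSmiles(structure)
  if (!is(structure, "MolecularGraph"))
    stop(errorCondition(paste0("residue ", code,
      ": structure must be a SMILES string or MolecularGraph ",
      "(quote SMILES like N or Y in YAML files)"),
      class = c("mf_alphabet_error", "mf_error")))
  asSpecs <- function(x) {
    if (is.character(x)) lapply(x, parseAtomSpec) else x
  }
  r <- new("Residue", code = code, id = id, name = name, structure = structure,
    lBondAtoms = asSpecs(lBondAtoms), rBondAtoms = asSpecs(rBondAtoms),
    lDisplacedAtoms = asSpecs(lDisplacedAtoms),
    rDisplacedAtoms = asSpecs(rDisplacedAtoms),
    baseMonomers = baseMonomers, aliases = aliases,
    xrefs = as.list(xrefs), comments = comments)
  for (spec in c(r@lBondAtoms, r@rBondAtoms, r@lDisplacedAtoms,
      r@rDisplacedAtoms)) {
    tryCatch(resolveAtomSpec(r@structure, spec), error = function(e)
      stop(errorCondition(
        sprintf("residue %s: atom reference %s does not resolve: %s",
          code, formatAtomSpec(spec), conditionMessage(e)),
        class = c("mf_alphabet_error", "mf_error"))))
  }
  r
}

isLeftCap <- function(r) length(r@lBondAtoms) == 0L
isRightCap <- function(r) length(r@rBondAtoms) == 0L

setMethod("show", "Residue", function(object) {
  cat(sprintf("Residue %s (%s): %s | %s | l-bond [%s] r-bond [%s]\n",
    object@code, object@id, object@name,
    formulaString(getFormula(object@structure)),
    paste(vapply(object@lBondAtoms, formatAtomSpec, ""), collapse = ","),
    paste(vapply(object@rBondAtoms, formatAtomSpec, ""), collapse = ",")))
})

#' Construct an alphabet
#'
#' @param id,name,type alphabet identity; `type` is `"DNA"`, `"RNA"`, or
#'   `"protein"`
#' @param residues list of [Residue-class]; keyed by their codes
#' @return an [Alphabet-class]
#' @export
alphabet <- function(id, name, type, residues) {
  names(residues) <- vapply(residues, function(r) r@code, "")
  if (anyDuplicated(names(residues)))
    stop(errorCondition(paste0("duplicate residue code(s): ",
      paste(unique(names(residues)[duplicated(names(residues))]), collapse = ", ")),
      class = c("mf_alphabet_error", "mf_error")))
  new("Alphabet", id = id, name = name, type = type, residues = residues)
}

setMethod("show", "Alphabet", function(object) {
  cat(sprintf("Alphabet %s (%s): %d residues [%s]\n", object@id, object@type,
    length(object@residues), paste(names(object@residues), collapse = " ")))
})

#' Look up a residue by code
#'
#' Codes and aliases are case-sensitive. Unknown codes raise an error
#' naming the nearest codes by edit distance.
#'
#' @param a an [Alphabet-class]
#' @param code residue code or alias
#' @return a [Residue-class]
#' @export
getResidue <- function(a, code) {
  stopifnot(is(a, "Alphabet"))
  if (code %in% names(a@residues)) return(a@residues[[code]])
  for (r in a@residues) if (code %in% r@aliases) return(r)
  all_codes <- names(a@residues)
  d <- utils::adist(code, all_codes)[1, ]
  near <- all_codes[order(d)][seq_len(min(3L, length(all_codes)))]
  stop(errorCondition(
    sprintf("unknown residue code '%s' in alphabet %s; nearest codes: %s",
      code, a@id, paste(near, collapse = ", ")),
    class = c("mf_unknown_code", "mf_error")))
}

#' The unknown-residue code of an alphabet type
#'
#' `"N"` for DNA/RNA, `"X"` for protein; used when exporting the canonical
#' sequence of a residue with no recorded base monomers.
#'
#' @param a an [Alphabet-class]
#' @return single character
#' @export
unknownCode <- function(a) if (a@type == "protein") "X" else "N"

.specsFromYaml <- function(x) {
  if (is.null(x)) list() else lapply(as.character(x), parseAtomSpec)
}
.specsToYaml <- function(x) {
  if (length(x) == 0L) NULL else vapply(x, formatAtomSpec, "")
}

#' Load an alphabet from a YAML file
#'
#' The schema stores one alphabet per document with `id`, `name`, `type`,
#' and a `residues` list whose entries carry `code`, `structure` (SMILES,
#' stored verbatim), the four atom-spec lists in compact text form,
#' `base_monomers`, `aliases`, `xrefs`, and `comments`. Loading validates
#' every atom reference against the residue structure; save followed by
#' load is the identity.
#'
#' @param path file path
#' @return an [Alphabet-class]
#' @seealso [saveAlphabet()], [builtinAlphabet()]
#' @export
loadAlphabet <- function(path) {
  doc <- yaml::read_yaml(path)
  for (field in c("id", "type", "residues"))
    if (is.null(doc[[field]]))
      stop(errorCondition(paste0("alphabet file missing field '", field, "'"),
        class = c("mf_alphabet_error", "mf_error")))
  residues <- lapply(doc$residues, function(entry) {
    if (is.null(entry$code) || is.null(entry$structure))
      stop(errorCondition("residue entry missing code or structure",
        class = c("mf_alphabet_error", "mf_error")))
    residue(code = as.character(entry$code), structure = entry$structure,
      id = if (is.null(entry$id)) as.character(entry$code) else entry$id,
      name = if (is.null(entry$name)) as.character(entry$code) else entry$name,
      lBondAtoms = .specsFromYaml(entry$l_bond_atoms),
      rBondAtoms = .specsFromYaml(entry$r_bond_atoms),
      lDisplacedAtoms = .specsFromYaml(entry$l_displaced_atoms),
      rDisplacedAtoms = .specsFromYaml(entry$r_displaced_atoms),
      baseMonomers = as.character(entry$base_monomers %||% character()),
      aliases = as.character(entry$aliases %||% character()),
      xrefs = as.character(entry$xrefs %||% character()),
      comments = as.character(entry$comments %||% character()))
  })
  alphabet(doc$id, doc$name %||% doc$id, doc$type, residues)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Save an alphabet to a YAML file
#'
#' @param a an [Alphabet-class]
#' @param path file path
#' @return invisibly, `path`
#' @export
saveAlphabet <- function(a, path) {
  stopifnot(is(a, "Alphabet"))
  doc <- list(id = a@id, name = a@name, type = a@type,
    residues = lapply(unname(a@residues), function(r) {
      entry <- list(code = r@code, id = r@id, name = r@name,
        structure = writeSmiles(r@structure),
        l_bond_atoms = .specsToYaml(r@lBondAtoms),
        r_bond_atoms = .specsToYaml(r@rBondAtoms),
        l_displaced_atoms = .specsToYaml(r@lDisplacedAtoms),
        r_displaced_atoms = .specsToYaml(r@rDisplacedAtoms),
        base_monomers = if (length(r@baseMonomers)) r@baseMonomers else NULL,
        aliases = if (length(r@aliases)) r@aliases else NULL,
        xrefs = if (length(r@xrefs)) unlist(r@xrefs) else NULL,
        comments = if (length(r@comments)) r@comments else NULL)
      entry[!vapply(entry, is.null, TRUE)]
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Construct a crosslink type
#'
#' @param id,name identity
#' @param lBondAtoms,rBondAtoms,lDisplacedAtoms,rDisplacedAtoms atom specs
#'   (lists, or character vectors in compact form), interpreted relative to
#'   the residue occupying the left/right slot
#' @param allowedL,allowedR residue codes allowed in each slot; empty
#'   means unconstrained
#' @return a [CrosslinkType-class]
#' @export
crosslinkType <- function(id, name = id, lBondAtoms, rBondAtoms,
    lDisplacedAtoms = list(), rDisplacedAtoms = list(),
    allowedL = character(), allowedR = character()) {
  asSpecs <- function(x) if (is.character(x)) lapply(x, parseAtomSpec) else x
  new("CrosslinkType", id = id, name = name,
    lBondAtoms = asSpecs(lBondAtoms), rBondAtoms = asSpecs(rBondAtoms),
    lDisplacedAtoms = asSpecs(lDisplacedAtoms),
    rDisplacedAtoms = asSpecs(rDisplacedAtoms),
    allowedL = allowedL, allowedR = allowedR)
}

#' Load a crosslink ontology from a YAML file
#'
#' Entries carry `id`, `name`, the four atom-spec lists, and optional
#' `allowed_l`/`allowed_r` residue-code constraints. Duplicate ids are an
#' error.
#'
#' @param path file path
#' @return a [CrosslinkOntology-class]
#' @export
loadOntology <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$crosslinks))
    stop(errorCondition("ontology file missing field 'crosslinks'",
      class = c("mf_alphabet_error", "mf_error")))
  types <- lapply(doc$crosslinks, function(entry) {
    crosslinkType(id = entry$id, name = entry$name %||% entry$id,
      lBondAtoms = .specsFromYaml(entry$l_bond_atoms),
      rBondAtoms = .specsFromYaml(entry$r_bond_atoms),
      lDisplacedAtoms = .specsFromYaml(entry$l_displaced_atoms),
      rDisplacedAtoms = .specsFromYaml(entry$r_displaced_atoms),
      allowedL = as.character(entry$allowed_l %||% character()),
      allowedR = as.character(entry$allowed_r %||% character()))
  })
  ids <- vapply(types, function(x) x@id, "")
  if (anyDuplicated(ids))
    stop(errorCondition(paste0("duplicate crosslink id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      class = c("mf_alphabet_error", "mf_error")))
  names(types) <- ids
  new("CrosslinkOntology", types = types)
}

#' Look up a crosslink type by id
#'
#' @param o a [CrosslinkOntology-class]
#' @param id crosslink id
#' @return a [CrosslinkType-class]
#' @export
getCrosslinkType <- function(o, id) {
  stopifnot(is(o, "CrosslinkOntology"))
  if (!id %in% names(o@types))
    stop(errorCondition(sprintf("unknown crosslink type '%s'; known: %s",
      id, paste(names(o@types), collapse = ", ")),
      class = c("mf_unknown_code", "mf_error")))
  o@types[[id]]
}

setMethod("show", "CrosslinkOntology", function(object) {
  cat(sprintf("CrosslinkOntology: %d types [%s]\n", length(object@types),
    paste(names(object@types), collapse = " ")))
})

#' Packaged fixture alphabets and crosslink ontology
#'
#' Curated subsets packaged with MacroForms: the canonical DNA, RNA, and
#' protein residues plus a handful of biologically common modified
#' residues and caps (N6-methyl-dAMP, 5-methyl-dCMP, pseudouridylate, a
#' 7-methylguanylate-style 5' cap, phosphoserine/-threonine/-tyrosine,
#' selenocysteine, 4-hydroxyproline, an amino-terminal acetyl cap), and an
#' ontology seeded with disulfide, lysine-glycine isopeptide, and
#' thioester crosslinks. Amino acids are stored as free amino acids
#' (peptide-bond formation displaces a hydroxyl and two hydrogens, net one
#' water); nucleotides as 5'-monophosphates (phosphodiester formation nets
#' one water).
#'
#' @param type `"dna"`, `"rna"`, or `"protein"` (case-insensitive)
#' @return [builtinAlphabet()]: an [Alphabet-class];
#'   [builtinOntology()]: a [CrosslinkOntology-class]
#' @export
builtinAlphabet <- function(type = c("protein", "dna", "rna")) {
  type <- tolower(match.arg(tolower(type), c("protein", "dna", "rna")))
  key <- paste0("alphabet_", type)
  if (is.null(.mf_env[[key]])) {
    path <- system.file("extdata", "alphabets", paste0(type, ".yml"),
      package = "MacroForms", mustWork = TRUE)
    .mf_env[[key]] <- loadAlphabet(path)
  }
  .mf_env[[key]]
}

#' @rdname builtinAlphabet
#' @export
builtinOntology <- function() {
  if (is.null(.mf_env$ontology)) {
    path <- system.file("extdata", "crosslinks.yml", package = "MacroForms",
      mustWork = TRUE)
    .mf_env$ontology <- loadOntology(path)
  }
  .mf_env$ontology
}
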