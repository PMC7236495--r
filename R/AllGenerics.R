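#' Chemical formula of a molecule
#'
#' Element counts of a molecular graph, polymer, or complex, including
#' implicit hydrogens. For polymers and complexes the described molecule is
#' assembled first (backbone bonds, crosslinks, displaced atoms removed).
#'
#' @param x a [MolecularGraph-class], [Polymer-class], or [ComplexForm-class]
#' @param ... further arguments for methods
#' @return named integer vector of element counts (an element formula);
#'   format it with [formulaString()]
#' @seealso [getMolWeight()], [getCharge()]
#' @export
setGeneric("getFormula", function(x, ...) standardGeneric("getFormula"))

#' Molecular weight in daltons
#'
#' Sum over the element formula of IUPAC standard (average) atomic weights
#' from the packaged table. For polymers/complexes any recorded extra
#' observed mass is added.
#'
#' @inheritParams getFormula
#' @return numeric, daltons
#' @export
setGeneric("getMolWeight", function(x, ...) standardGeneric("getMolWeight"))

#' Net formal charge
#'
#' Sum of atomic formal charges (plus any recorded extra observed charge
#' for polymers/complexes).
#'
#' @inheritParams getFormula
#' @return integer
#' @export
setGeneric("getCharge", function(x, ...) standardGeneric("getCharge"))

#' Assemble a described molecule into a molecular graph
#'
#' Realizes the bonds a polymer or complex description encodes: the residue
#' structures are placed side by side, displaced atoms are removed (an
#' implicit hydrogen is decremented from its heavy atom; displaced heavy
#' atoms are deleted together with their implicit hydrogens), and single
#' bonds are added between the paired bond atoms of each backbone bond and
#' crosslink. Nicks and uncertainty metadata contribute no bonds.
#'
#' @param x a validated [Polymer-class] or [ComplexForm-class]
#' @param ... further arguments for methods
#' @return a [MolecularGraph-class]
#' @export
setGeneric("assemble", function(x, ...) standardGeneric("assemble"))

#' Serialize a polymer or complex back to its textual description
#'
#' Deterministic inverse of [parsePolymer()] / [parseComplex()]:
#' re-parsing the output yields a structurally equal object.
#'
#' @param x a [Polymer-class] or [ComplexForm-class]
#' @param ... further arguments for methods
#' @return single character string
#' @export
setGeneric("serializeForm", function(x, ...) standardGeneric("serializeForm"))

#' Structural equality of described molecules
#'
#' Two descriptions are equal when their normalized canonical
#' serializations are identical: inline-defined residues are matched to
#' alphabet residues by structure isomorphism where possible, and complex
#' equality holds up to permutation of the interchangeable copies of each
#' subunit.
#'
#' @param a,b two [Polymer-class] or two [ComplexForm-class] objects
#' @param ... further arguments for methods
#' @return logical
#' @seealso [molDiff()]
#' @export
setGeneric("molEqual", function(a, b, ...) standardGeneric("molEqual"))

#' Structured differences between two described molecules
#'
#' Positionwise sequence comparison (not a full edit distance) plus
#' crosslink and attribute discrepancies. Empty if and only if
#' [molEqual()] is TRUE.
#'
#' @inheritParams molEqual
#' @return data.frame with columns `kind`, `location`, `a`, `b`, `message`
#' @export
setGeneric("molDiff", function(a, b, ...) standardGeneric("molDiff"))

#' Export an assembled molecule as SMILES
#'
#' `writeSmiles(assemble(x))`; components disconnected by nicks are emitted
#' as dot-separated SMILES components.
#'
#' @param x a validated [Polymer-class] or [ComplexForm-class]
#' @param ... further arguments for methods
#' @return single SMILES string
#' @export
setGeneric("exportSmiles", function(x, ...) standardGeneric("exportSmiles"))
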