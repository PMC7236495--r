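---
title: "MacroForms: data model, chemistry conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MacroForms: data model, chemistry conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MacroForms)
```

## The three-layer model

MacroForms describes a macromolecule at three levels. A **complex** is a
set of subunits with stoichiometries plus inter-subunit crosslinks. A
**polymer** is a sequence of residue occurrences, a set of nicks (a nick
at position *i* means no backbone bond between residues *i* and *i+1*),
a list of intra-chain crosslinks, a circularity flag, and uncertainty
metadata. A **residue** is a molecular structure (SMILES) together with
the atoms that form bonds with the preceding (left) and following
(right) residue, and the atoms displaced when those bonds form. Caps are
simply residues with an empty bond-atom list on one side, which confines
them to chain ends. Crosslink types in the ontology carry the same
atom-level information, interpreted relative to the residues occupying
their left/right slots.

Atoms are addressed hierarchically: subunit id and copy number → residue
position → element symbol plus 1-based index into the residue
structure's stored atom order. We pin atom coordinates to the order of
first appearance in the stored SMILES string rather than to any
canonicalizer's output: that order is deterministic, toolkit-independent,
and survives serialization round trips. Implicit hydrogens are not
indexed; a displaced hydrogen is written `H5`, meaning "one hydrogen on
heavy atom 5". Consequently atom indices are only comparable between
tools that store the same SMILES text, which is why alphabet files keep
SMILES verbatim.

## Bond chemistry conventions

The data model does not hard-code any bond chemistry; the fixtures do,
and these are the conventions a user extending the alphabets should
follow.

Amino acids are stored as free amino acids on the uniform scaffold
`OC(=O)C(N)…` so the backbone atoms share indices across residues: the
carboxyl carbon is atom `C2` (right bond atom; displaces hydroxyl `O1`
and its hydrogen `H1`), the α-amine is `N5` (left bond atom; displaces
`H5`). One water leaves per peptide bond. Proline and 4-hydroxyproline
put the ring nitrogen at `N8`/`N9`; side chains always follow the
backbone, so the cysteine thiol is `S7` and the lysine ε-nitrogen `N10`
— the indices the crosslink ontology uses. Nucleotides are stored as
5′-monophosphates written phosphate-first: the phosphorus `P2` is the
left bond atom (displacing `O1`/`H1`), the 3′-oxygen (`O12` for DNA,
`O13` for RNA) the right bond atom (displacing its hydrogen); a
phosphodiester bond also nets one water. Backbone and crosslink bonds
are single bonds; multi-atom bond specifications pair by list order.

When a displaced list names a heavy atom and a hydrogen on it (`O1`,
`H1`), assembly removes one O and one H in total: hydrogen displacements
decrement the heavy atom's implicit count first, then displaced heavy
atoms leave with whatever hydrogens they still carry. The test suite's
arithmetic oracle re-implements exactly this bookkeeping on element
counts alone, never touching a graph, which is what makes the
formula-conservation property a genuine two-route check.

## The SMILES subset

The molecular layer implements its own minimal SMILES reader/writer
because atom coordinates must be pinned to the stored text (a
general-purpose toolkit would re-canonicalize). Supported: organic-subset
atoms, bracket atoms with explicit hydrogen counts and charges, bond
symbols `- = # :`, branches, ring closures (including `%nn`), dots, and
aromatic lowercase atoms. Stereochemistry is rejected (primary structure
does not need it); bracket isotopes parse and are ignored with a
warning. Aromatic input is kekulized by assigning one double bond to
every aromatic atom whose valence is otherwise unsatisfied, via a
backtracking perfect matching over the aromatic bonds; an odd or
unmatched system is an error. Implicit hydrogens of organic-subset atoms
follow the standard default valences (B 3; C 4; N 3/5; O 2; P 3/5;
S 2/4/6; halogens 1). `writeSmiles()` emits depth-first from atom 1 with
neighbors in ascending index order — deterministic without a full
canonicalization algorithm — and always writes Kekulé structures.
Molecular weights use the packaged table of IUPAC standard (average)
atomic weights; monoisotopic masses are out of scope. Weight comparisons
throughout use a 0.01 Da tolerance.

## Grammars

The polymer grammar is a sequence of units — a single-letter code, a
longer code in braces (`{SEC}`), an inline residue definition in square
brackets, or `:` for a nick — followed by `|`-separated attributes:
`circular`, `x-link: […]`, `extra: [mass: … | charge: …]`, and
`comments: "…"`. Crosslinks are either ontology-typed
(`type: disulfide | l: 2 | r: 5`) or explicit atom lists
(`l-bond-atom: 2S7 | …`). Inline definitions carry `id`, `structure`
(quoted SMILES, kept verbatim through serialization), repeatable
bond/displaced-atom fields, `base-monomer`, an optional `position: lo-hi`
uncertainty range, and `comments`. A residue whose location is uncertain
is written at a concrete anchor position with a range attribute, keeping
sequence length well-defined. Whitespace is insignificant outside
quotes; the grammar is case-sensitive. Parse errors report line, column,
and the expected tokens.

The complex grammar is `n * id` terms joined by `+`, plus `x-link`
attributes whose slots read `id(copy)-position` (optionally followed by
`element index` for explicit atoms). Subunit structures arrive
out-of-band (a mapping), mirroring the layering above. Copies of a
subunit are interchangeable except as distinguished by crosslinks, so
equality searches copy permutations exhaustively; the search is capped
at stoichiometry 8 (an error beyond), far above the fixtures' ≤ 4.

Two open points were decided as follows: a crosslink spanning a nick is
accepted with a warning (the chemistry is well-defined; the description
is merely unusual), and a "complex" of one subunit with stoichiometry 1
and no crosslinks parses with a warning rather than an error. Extra
observed mass/charge contribute to molecular weight and charge but
cannot contribute to the element formula, which has no elements to give
them.

## Validation rules

`validatePolymer()` reports findings, never throws. The rules: **V1**
every bonded adjacent pair is bondable; **V2** left caps only at
position 1 or right of a nick, right caps only at the final position or
left of a nick, no caps in circular polymers; **V3** circular closure
requires bondable ends; **V4** every atom reference resolves with the
expected element (the element symbol in a coordinate is deliberately
redundant — it is the guard that catches index drift) and bond-atom
lists pair up; **V5** displaced hydrogens must exist, counting all
displacements per atom; **V6** crosslink coordinates in range; **V7**
ontology crosslinks respect their allowed residue codes; **V8** no atom
consumed by two bonds; **V9** uncertainty ranges inside the sequence and
bracketing their anchor. A report with no errors is exactly the
condition under which `assemble()` succeeds. A misplaced cap fires both
V1 (its neighbor pair) and V2 (its position); both are truthful and both
are reported. `validateComplex()` runs the polymer rules per subunit and
the crosslink rules at complex scope (existence of subunit ids, copy ≤
stoichiometry, per-subunit residue ranges, V4/V5/V7/V8 across all
expanded copies).

Reference QC (`checkAgainstReference()`) compares each residue's base
monomers against a canonical sequence. Residues with no recorded base
monomers are wildcards that warn rather than fail — an unknown-origin
residue should not hard-fail an audit. The `offset` argument reconciles
coordinates reported against a translated sequence with references that
have lost their initiator methionine (offset 1 shifts the reference
index by one).

## Equality and diff

Equality is identical canonical serialization after normalization:
inline residues collapse onto an alphabet residue when their structures
are graph-isomorphic and their atom references identical; aliases
resolve to registry codes; crosslinks sort canonically. Diff is a
positionwise comparison (sequence edits by position, crosslink set
differences, attribute changes), not an edit distance — registry QC
wants "position 3 differs", not a minimal rewrite script. For complexes
the crosslink multiset is canonicalized by exhaustive copy relabeling
before comparison, so `l: pep(1) … r: pep(2)` equals
`l: pep(2) … r: pep(1)`.

## The corpus generator

`generateCorpus()` emulates the descriptions this tooling meets in
practice: protein chains of 5–15 residues (the scale of tryptic peptides
and modification neighborhoods), each position modified with probability
0.2, and per-record nick/crosslink/circularity features at 0.2/0.2/0.1 —
frequent enough that every grammar feature appears hundreds of times in
a thousand records, which is what the round-trip and conservation
properties need. Defect corpora inject exactly one labeled defect per
record, round-robin over V1–V9 so every rule is covered evenly. What the
generator does *not* emulate: realistic amino-acid composition,
biologically plausible modification co-occurrence, or the long (> 1000
residue) proteins of real registries. Passing tests therefore
demonstrate correctness of parsing, validation, and assembly over the
grammar's feature space, not performance or realism at proteome scale.
The generator saves and restores the caller's RNG state, so a seed fixes
its output exactly without disturbing the session.

Problem sizes used by the acceptance checks — 1000 polymers for the
conservation and round-trip properties, 200 complexes, 450-record defect
and clean corpora (50 per rule), 100 cases for duality and backward
compatibility, glycine chains to n = 50 — were chosen so every
combinatorial feature interaction is exercised many times while the
whole suite stays comfortably interactive.

## Numerical and degenerate-input choices

Atomic weights come from a packaged table generated from a
cheminformatics toolkit's periodic table (IUPAC standard atomic
weights); the same toolkit's formula/weight/charge values for all 38
fixture residues are frozen in `inst/extdata/golden_properties.tsv` and
compared in the tests at 0.01 Da. Empty graphs have no molecular weight
(error) and empty SMILES is a parse error, as is a polymer with zero
residues. Circular requires length ≥ 2. Nick positions live in 1..n−1
(1..n when circular, where a nick at n severs the closing bond).
Duplicate nicks and self-crosslinks are parse errors. Hill order governs
formula rendering (C, H, then alphabetical; fully alphabetical without
carbon).

## Known limitations

- Charges are the formal charges of the stored structures; protonation
  and tautomer state prediction is out of scope, so weights and charges
  correspond to the neutral-pH-agnostic forms the alphabets store.
- Atom indices are tied to the stored SMILES text; interoperability of
  numeric indices with tools that canonicalize differently is not
  guaranteed (the element guard in every coordinate catches most
  accidents).
- The fixture alphabets are curated subsets, not the thousands of
  modified residues in public databases; the file format is designed for
  users to extend.
- The 7-methylguanylate cap fixture models the capped residue itself;
  the physiological 5′–5′ triphosphate bridge is not represented.
- Monoisotopic masses, stereochemistry, and 3D structure are out of
  scope.
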