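# MacroForms

Concrete representation of the primary structure of DNA, RNA, proteins,
and their complexes — including the chemistry the Central Dogma leaves
out: non-canonical (modified) residues, 5′ caps and other terminal caps,
crosslinks such as disulfide and isopeptide bonds, nicks, and circular
chains.

Plain sequence formats (IUPAC/IUBMB one-letter strings, FASTA) cannot say
*which* phosphoserine sits at position 2 or that two cysteines are
disulfide-bonded; full molecular formats (SMILES) can, but a 300-residue
proteoform written atom-by-atom is unusable for network research.
MacroForms sits between the two, for omics researchers doing quality
control of proteoform/modification registries, systems biologists
assembling whole-cell models that track post-transcriptional and
post-translational state, and bioengineers specifying designed molecules.

## The model

A molecule is described in three layers:

1. **Complexes** are bags of subunits with stoichiometries plus
   inter-subunit crosslinks: `2 * pep | x-link: [type: disulfide |
   l: pep(1)-2 | r: pep(2)-2]`.
2. **Polymers** are sequences of residues with nicks (`:`), intra-chain
   crosslinks, a circularity flag, and uncertainty metadata (position
   ranges, extra observed mass/charge): `AC{SEC}`, `AA:GG`,
   `ACGT | circular`.
3. **Residues** couple a molecular structure (SMILES) with the atoms that
   bond the preceding/following residue and the atoms displaced when
   those bonds form. A residue with no left bond atoms is a left cap. A
   hierarchical coordinate system — subunit id/copy → residue position →
   element + atom index in the stored SMILES atom order — addresses any
   atom, e.g. the cysteine thiol sulfur `pep(1)-2S7`.

Because every residue and crosslink is chemically concrete, a described
molecule can be *assembled* into an atom/bond graph, so the package
computes exact element formulas, average molecular weights, and net
formal charges (`getFormula()`, `getMolWeight()`, `getCharge()`), checks
element balance of reactions built from these species, compares molecules
(`molEqual()`, `molDiff()`), and exports SMILES, canonical IUPAC/IUBMB
sequences, and FASTA. Nine semantic rules (V1–V9) catch descriptions that
look fine but cannot exist — caps mid-chain, crosslinks whose coordinates
exceed the sequence, atom references naming the wrong element, hydrogens
displaced twice — and a reference-QC check catches modified residues
inconsistent with their parent sequence.

Packaged fixtures provide the canonical DNA/RNA/protein alphabets plus
curated modified residues (N6-methyl-dAMP, 5-methyl-dCMP,
pseudouridylate, a 7-methylguanylate-style 5′ cap, phospho-Ser/Thr/Tyr,
selenocysteine, 4-hydroxyproline, an N-terminal acetyl cap) and a seed
crosslink ontology (disulfide, lysine–glycine isopeptide, thioester).
Alphabets and ontologies are plain YAML and fully user-extensible;
residues can also be defined inline inside a description.

## Worked example

A selenocysteine-containing tripeptide and its disulfide-linked homodimer:

```r
library(MacroForms)

pep <- parsePolymer("AC{SEC}", "protein")
formulaString(getFormula(pep))   # "C9H17N3O4SSe"
round(getMolWeight(pep), 2)      # 342.28 (Da)
getCharge(pep)                   # 0
canonicalSequence(pep)           # "ACU"

cx <- parseComplex(
  "2 * pep | x-link: [type: disulfide | l: pep(1)-2 | r: pep(2)-2]",
  subunits = list(pep = pep))
validateComplex(cx)              # ValidationReport: 0 error(s), 0 warning(s)
formulaString(getFormula(cx))    # "C18H32N6O8S2Se2"
round(getMolWeight(cx), 2)       # 682.54
```

Two copies of the tripeptide (2 × 342.28 Da) lose two thiol/selenol-side
hydrogens on forming the S–S bond: 682.54 Da. Semantic validation and
registry QC in action:

```r
validatePolymer(parsePolymer(
  "ACD | x-link: [type: disulfide | l: 2 | r: 9]", "protein"))
# ValidationReport: 1 error(s), 0 warning(s)
#   [error V6] crosslink 1: residue coordinate(s) 9 beyond the sequence length 3

checkAgainstReference(parsePolymer("A{pS}D", "protein"), "AYD")
# ValidationReport: 1 error(s), 0 warning(s)
#   [error Q2] residue 2: residue pS derives from S but the reference has Y at this position
```

A command-line interface wraps the same functions
(`inst/scripts/macroforms`): `validate`, `props`, `export --format
smiles|fasta|canonical-seq`, `qc --ref ref.fasta --offset N`, and
`gen-corpus`; exit code 0 means clean, 1 validation errors, 2 usage/parse
failure.

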