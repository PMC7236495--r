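Package: MacroForms
Title: Concrete Representation of Modified Biopolymers and Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents the primary structure of DNA, RNA, proteins, and
    their complexes as combinations of residues (including non-canonical
    residues and caps), backbone bonds, nicks, intra- and inter-chain
    crosslinks, and circularity. Provides extensible alphabets of residues
    and an ontology of crosslinks, human- and machine-readable grammars for
    polymers and complexes with parsers and serializers, semantic
    validation, assembly of described molecules into molecular graphs,
    calculation of chemical formula, molecular weight, and net charge,
    structural comparison, and export to SMILES and canonical IUPAC/IUBMB
    sequences and FASTA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
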