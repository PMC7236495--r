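# Seed ontology of common protein crosslinks. Atom references are
# interpreted relative to the structure of the residue occupying each slot
# (left/right), using the packaged protein-alphabet structures.
crosslinks:
- id: disulfide
  name: cystine disulfide bond
  l_bond_atoms: [S7]
  l_displaced_atoms: [H7]
  r_bond_atoms: [S7]
  r_displaced_atoms: [H7]
  allowed_l: ['C']
  allowed_r: ['C']
- id: isopeptide_K_G
  name: lysine-glycine isopeptide bond (pupylation/ubiquitylation style)
  l_bond_atoms: [N10]
  l_displaced_atoms: [H10]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  allowed_l: ['K']
  allowed_r: ['G']
- id: thioester
  name: cysteine-glycine thioester bond
  l_bond_atoms: [S7]
  l_displaced_atoms: [H7]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  allowed_l: ['C']
  allowed_r: ['G']
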