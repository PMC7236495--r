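id: dna
name: DNA residues (canonical deoxyribonucleotide monophosphates plus curated modified residues)
type: DNA
# Residues are stored as 2'-deoxyribonucleoside 5'-monophosphates written
# phosphate-first so the backbone atom indices are shared by every entry:
# the phosphodiester bond forms between the phosphorus P2 of the right
# residue (displacing hydroxyl O1 with its hydrogen) and the 3'-oxygen O12
# of the left residue (displacing its hydrogen); net loss one water.
residues:
- code: 'A'
  id: damp
  name: 2'-deoxyadenosine 5'-monophosphate
  structure: OP(=O)(O)OCC1OC(CC1O)n2cnc3c(N)ncnc23
  l_bond_atoms: [P2]
  l_displaced_atoms: [O1, H1]
  r_bond_atoms: [O12]
  r_displaced_atoms: [H12]
  base_monomers: ['A']
  xrefs: ['PDB-CCD:DA']
- code: 'C'
  id: dcmp
  name: 2'-deoxycytidine 5'-monophosphate
  structure: OP(=O)(O)OCC1OC(CC1O)n2ccc(N)nc2=O
  l_bond_atoms: [P2]
  l_displaced_atoms: [O1, H1]
  r_bond_atoms: [O12]
  r_displaced_atoms: [H12]
  base_monomers: ['C']
  xrefs: ['PDB-CCD:DC']
- code: 'G'
  id: dgmp
  name: 2'-deoxyguanosine 5'-monophosphate
  structure: OP(=O)(O)OCC1OC(CC1O)n2cnc3c(=O)[nH]c(N)nc23
  l_bond_atoms: [P2]
  l_displaced_atoms: [O1, H1]
  r_bond_atoms: [O12]
  r_displaced_atoms: [H12]
  base_monomers: ['G']
  xrefs: ['PDB-CCD:DG']
- code: 'T'
  id: dtmp
  name: thymidine 5'-monophosphate
  structure: OP(=O)(O)OCC1OC(CC1O)n2cc(C)c(=O)[nH]c2=O
  l_bond_atoms: [P2]
  l_displaced_atoms: [O1, H1]
  r_bond_atoms: [O12]
  r_displaced_atoms: [H12]
  base_monomers: ['T']
  xrefs: ['PDB-CCD:DT']
- code: 'm6A'
  id: m6damp
  name: N6-methyl-2'-deoxyadenosine 5'-monophosphate
  structure: OP(=O)(O)OCC1OC(CC1O)n2cnc3c(NC)ncnc23
  l_bond_atoms: [P2]
  l_displaced_atoms: [O1, H1]
  r_bond_atoms: [O12]
  r_displaced_atoms: [H12]
  base_monomers: ['A']
  xrefs: ['PDB-CCD:6MA']
  comments: restriction/modification mark distinguishing self from foreign DNA
- code: 'm5C'
  id: m5dcmp
  name: 5-methyl-2'-deoxycytidine 5'-monophosphate
  structure: OP(=O)(O)OCC1OC(CC1O)n2cc(C)c(N)nc2=O
  l_bond_atoms: [P2]
  l_displaced_atoms: [O1, H1]
  r_bond_atoms: [O12]
  r_displaced_atoms: [H12]
  base_monomers: ['C']
  xrefs: ['PDB-CCD:5CM']
  comments: the major eukaryotic epigenetic mark
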