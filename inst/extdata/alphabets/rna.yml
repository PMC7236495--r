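id: rna
name: RNA residues (canonical ribonucleotide monophosphates plus curated modified residues and a 5' cap)
type: RNA
# Residues are stored as ribonucleoside 5'-monophosphates written
# phosphate-first: phosphodiester formation bonds P2 of the right residue
# (displacing O1 and its hydrogen) to the 3'-oxygen O13 of the left
# residue (displacing its hydrogen); net loss one water.
residues:
- code: 'A'
  id: amp
  name: adenosine 5'-monophosphate
  structure: OP(=O)(O)OCC1OC(C(O)C1O)n2cnc3c(N)ncnc23
  l_bond_atoms: [P2]
  l_displaced_atoms: [O1, H1]
  r_bond_atoms: [O13]
  r_displaced_atoms: [H13]
  base_monomers: ['A']
  xrefs: ['PDB-CCD:A']
- code: 'C'
  id: cmp
  name: cytidine 5'-monophosphate
  structure: OP(=O)(O)OCC1OC(C(O)C1O)n2ccc(N)nc2=O
  l_bond_atoms: [P2]
  l_displaced_atoms: [O1, H1]
  r_bond_atoms: [O13]
  r_displaced_atoms: [H13]
  base_monomers: ['C']
  xrefs: ['PDB-CCD:C']
- code: 'G'
  id: gmp
  name: guanosine 5'-monophosphate
  structure: OP(=O)(O)OCC1OC(C(O)C1O)n2cnc3c(=O)[nH]c(N)nc23
  l_bond_atoms: [P2]
  l_displaced_atoms: [O1, H1]
  r_bond_atoms: [O13]
  r_displaced_atoms: [H13]
  base_monomers: ['G']
  xrefs: ['PDB-CCD:G']
- code: 'U'
  id: ump
  name: uridine 5'-monophosphate
  structure: OP(=O)(O)OCC1OC(C(O)C1O)n2ccc(=O)[nH]c2=O
  l_bond_atoms: [P2]
  l_displaced_atoms: [O1, H1]
  r_bond_atoms: [O13]
  r_displaced_atoms: [H13]
  base_monomers: ['U']
  xrefs: ['PDB-CCD:U']
- code: 'PSI'
  id: psiump
  name: pseudouridine 5'-monophosphate
  structure: OP(=O)(O)OCC1OC(C(O)C1O)c2c[nH]c(=O)[nH]c2=O
  l_bond_atoms: [P2]
  l_displaced_atoms: [O1, H1]
  r_bond_atoms: [O13]
  r_displaced_atoms: [H13]
  base_monomers: ['U']
  xrefs: ['PDB-CCD:PSU']
  comments: C-glycosidic uridine isomer; the most abundant tRNA modification
- code: 'm7G'
  id: m7gcap
  name: 7-methylguanylate 5' cap
  structure: OP(=O)(O)OCC1OC(C(O)C1O)N2C=[N+](C)C3=C2N=C(N)NC3=O
  r_bond_atoms: [O13]
  r_displaced_atoms: [H13]
  xrefs: ['PDB-CCD:M7G']
  comments: >-
    left cap (empty left bond-atom list); stabilizes eukaryotic mRNA.
    Modeled as the N7-methylated guanylate residue itself; the 5'-5'
    triphosphate bridge of the physiological cap is not represented.
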