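id: protein
name: Protein residues (canonical amino acids plus curated modified residues and caps)
type: protein
# Residues are stored as free amino acids. The peptide bond forms between
# the carboxyl carbon (C2) of the left residue and the amine nitrogen of
# the right residue; it displaces the hydroxyl oxygen O1 with its hydrogen
# on the left and one amine hydrogen on the right (net loss: one water).
# All side chains are written after the backbone so that the backbone atom
# indices are identical across residues (amine N5 except proline N8,
# hydroxyproline N9).
residues:
- code: 'G'
  id: gly
  name: glycine
  structure: OC(=O)CN
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['G']
  xrefs: ['PDB-CCD:GLY']
- code: 'A'
  id: ala
  name: alanine
  structure: OC(=O)C(N)C
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['A']
  xrefs: ['PDB-CCD:ALA']
- code: 'V'
  id: val
  name: valine
  structure: OC(=O)C(N)C(C)C
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['V']
  xrefs: ['PDB-CCD:VAL']
- code: 'L'
  id: leu
  name: leucine
  structure: OC(=O)C(N)CC(C)C
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['L']
  xrefs: ['PDB-CCD:LEU']
- code: 'I'
  id: ile
  name: isoleucine
  structure: OC(=O)C(N)C(C)CC
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['I']
  xrefs: ['PDB-CCD:ILE']
- code: 'P'
  id: pro
  name: proline
  structure: OC(=O)C1CCCN1
  l_bond_atoms: [N8]
  l_displaced_atoms: [H8]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['P']
  xrefs: ['PDB-CCD:PRO']
- code: 'F'
  id: phe
  name: phenylalanine
  structure: OC(=O)C(N)Cc1ccccc1
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['F']
  xrefs: ['PDB-CCD:PHE']
- code: 'W'
  id: trp
  name: tryptophan
  structure: OC(=O)C(N)Cc1c[nH]c2ccccc12
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['W']
  xrefs: ['PDB-CCD:TRP']
- code: 'M'
  id: met
  name: methionine
  structure: OC(=O)C(N)CCSC
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['M']
  xrefs: ['PDB-CCD:MET']
- code: 'S'
  id: ser
  name: serine
  structure: OC(=O)C(N)CO
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['S']
  xrefs: ['PDB-CCD:SER']
- code: 'T'
  id: thr
  name: threonine
  structure: OC(=O)C(N)C(C)O
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['T']
  xrefs: ['PDB-CCD:THR']
- code: 'C'
  id: cys
  name: cysteine
  structure: OC(=O)C(N)CS
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['C']
  xrefs: ['PDB-CCD:CYS']
- code: 'Y'
  id: tyr
  name: tyrosine
  structure: OC(=O)C(N)Cc1ccc(O)cc1
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['Y']
  xrefs: ['PDB-CCD:TYR']
- code: 'N'
  id: asn
  name: asparagine
  structure: OC(=O)C(N)CC(N)=O
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['N']
  xrefs: ['PDB-CCD:ASN']
- code: 'Q'
  id: gln
  name: glutamine
  structure: OC(=O)C(N)CCC(N)=O
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['Q']
  xrefs: ['PDB-CCD:GLN']
- code: 'D'
  id: asp
  name: aspartate
  structure: OC(=O)C(N)CC(O)=O
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['D']
  xrefs: ['PDB-CCD:ASP']
- code: 'E'
  id: glu
  name: glutamate
  structure: OC(=O)C(N)CCC(O)=O
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['E']
  xrefs: ['PDB-CCD:GLU']
- code: 'K'
  id: lys
  name: lysine
  structure: OC(=O)C(N)CCCCN
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['K']
  xrefs: ['PDB-CCD:LYS']
- code: 'R'
  id: arg
  name: arginine
  structure: OC(=O)C(N)CCCNC(N)=N
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['R']
  xrefs: ['PDB-CCD:ARG']
- code: 'H'
  id: his
  name: histidine
  structure: OC(=O)C(N)Cc1cnc[nH]1
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['H']
  xrefs: ['PDB-CCD:HIS']
- code: 'U'
  id: sec
  name: selenocysteine
  structure: OC(=O)C(N)C[SeH]
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['U']
  aliases: ['SEC']
  xrefs: ['PDB-CCD:SEC']
- code: 'pS'
  id: pser
  name: O-phosphoserine
  structure: OC(=O)C(N)COP(O)(O)=O
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['S']
  xrefs: ['PDB-CCD:SEP']
- code: 'pT'
  id: pthr
  name: O-phosphothreonine
  structure: OC(=O)C(N)C(C)OP(O)(O)=O
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['T']
  xrefs: ['PDB-CCD:TPO']
- code: 'pY'
  id: ptyr
  name: O-phosphotyrosine
  structure: OC(=O)C(N)Cc1ccc(OP(O)(O)=O)cc1
  l_bond_atoms: [N5]
  l_displaced_atoms: [H5]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['Y']
  xrefs: ['PDB-CCD:PTR']
- code: 'HYP'
  id: hyp
  name: 4-hydroxyproline
  structure: OC(=O)C1CC(O)CN1
  l_bond_atoms: [N9]
  l_displaced_atoms: [H9]
  r_bond_atoms: [C2]
  r_displaced_atoms: [O1, H1]
  base_monomers: ['P']
  xrefs: ['PDB-CCD:HYP']
- code: 'ACE'
  id: ace
  name: amino-terminal acetyl cap
  structure: CC(O)=O
  r_bond_atoms: [C2]
  r_displaced_atoms: [O3, H3]
  xrefs: ['PDB-CCD:ACE']
  comments: left cap; acylates the amino terminus of the following residue
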