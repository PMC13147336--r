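# Default topology registry: deuteroporphyrin IX (heme-like atom naming,
# IUPAC ring-position numbering for the nitrogens) plus nonstandard residue
# codes. User files with the same layout extend or override these entries.
porphyrin:
  residue_name: DPX
  metal_atom: CO
  ring_atoms: [N21, N22, N23, N24,
               C1, C2, C3, C4, C6, C7, C8, C9,
               C11, C12, C13, C14, C16, C17, C18, C19,
               C5, C10, C15, C20]
  meso_atoms:
    "5": C5
    "10": C10
    "15": C15
    "20": C20
  substituents:
    "2": [CAA, CBA, CGA]
    "3": [CMA]
    "7": [CMB]
    "8": [H8]
    "12": [CMC]
    "13": [H13]
    "17": [CMD]
    "18": [CAD, CBD, CGD]
  propionyl_attachment:
    "2": [CAA, CBA, CGA]
    "18": [CAD, CBD, CGD]
residues:
  AIB: alpha-aminoisobutyric acid (two beta methyls CB1/CB2)
  DAB: 2,4-diaminobutyric acid (side chain CB-CG-ND)
  DPX: deuteroporphyrin IX macrocycle
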