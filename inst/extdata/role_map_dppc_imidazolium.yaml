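# Example role map for the synthetic DPPC / imidazolium bead naming.
# Sections are roles; entries map (residue, bead) pairs to that role.
phosphate:
  - {residue: DPPC, bead: PO4}
lipid_other:
  - {residue: DPPC, bead: GL}
lipid_tail:
  - {residue: DPPC, bead: C1A}
  - {residue: DPPC, bead: C2A}
  - {residue: DPPC, bead: C3A}
  - {residue: DPPC, bead: C4A}
  - {residue: DPPC, bead: C1B}
  - {residue: DPPC, bead: C2B}
  - {residue: DPPC, bead: C3B}
  - {residue: DPPC, bead: C4B}
cation_head:
  - {residue: IMI, bead: RNG}
cation_tail:
  - {residue: IMI, bead: CT1}
  - {residue: IMI, bead: CT2}
  - {residue: IMI, bead: CT3}
  - {residue: IMI, bead: CT4}
anion:
  - {residue: BF4, bead: ANI}
water:
  - {residue: W, bead: W}
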