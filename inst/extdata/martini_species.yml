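# Default lipid species table: residue name -> species label, headgroup
# bead names, contact cutoff (nm). Mirrors default_species().
POPC: {species: PC,   headgroup_beads: [NC3, PO4],               cutoff: 0.65}
POPE: {species: PE,   headgroup_beads: [NH3, PO4],               cutoff: 0.65}
POPS: {species: PS,   headgroup_beads: [CNO, PO4],               cutoff: 0.65}
POP2: {species: PIP2, headgroup_beads: [C1, C2, C3, P1, P2, P3], cutoff: 0.65}
DPSM: {species: Sph,  headgroup_beads: [NC3, PO4],               cutoff: 0.65}
DPG3: {species: GM3,  headgroup_beads: [GM1, GM2, GM3, GM4, GM5, GM6], cutoff: 0.65}
CHOL: {species: CHOL, headgroup_beads: [ROH, R1, R2, R3, R4, R5], cutoff: 1.0}
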