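# Example force-field descriptor with approximate Martini-style bead radii
# (regular beads ~2.64 A, small beads ~2.30 A). The anchor/reference bead is
# the glycerol-backbone GL2 bead. Radii are force-field specific: adjust to
# the parameter set actually simulated before quantitative use.
DPPC:
  anchor: GL2
  reference: GL2
  beads:
    NC3: {radius: 2.64, class: polar}
    PO4: {radius: 2.64, class: polar}
    GL1: {radius: 2.64, class: polar}
    GL2: {radius: 2.64, class: polar}
    C1A: {radius: 2.64, class: aliphatic}
    C2A: {radius: 2.64, class: aliphatic}
    C3A: {radius: 2.64, class: aliphatic}
    C4A: {radius: 2.64, class: aliphatic}
    C1B: {radius: 2.64, class: aliphatic}
    C2B: {radius: 2.64, class: aliphatic}
    C3B: {radius: 2.64, class: aliphatic}
    C4B: {radius: 2.64, class: aliphatic}
  tails: [C1A, C2A, C3A, C4A, C1B, C2B, C3B, C4B]
POPC:
  anchor: GL2
  reference: GL2
  beads:
    NC3: {radius: 2.64, class: polar}
    PO4: {radius: 2.64, class: polar}
    GL1: {radius: 2.64, class: polar}
    GL2: {radius: 2.64, class: polar}
    C1A: {radius: 2.64, class: aliphatic}
    D2A: {radius: 2.64, class: aliphatic}
    C3A: {radius: 2.64, class: aliphatic}
    C4A: {radius: 2.64, class: aliphatic}
    C1B: {radius: 2.64, class: aliphatic}
    C2B: {radius: 2.64, class: aliphatic}
    C3B: {radius: 2.64, class: aliphatic}
    C4B: {radius: 2.64, class: aliphatic}
  tails: [C1A, D2A, C3A, C4A, C1B, C2B, C3B, C4B]
DLIP:
  anchor: GL2
  reference: GL2
  beads:
    NC3: {radius: 2.64, class: polar}
    PO4: {radius: 2.64, class: polar}
    GL1: {radius: 2.64, class: polar}
    GL2: {radius: 2.64, class: polar}
    D1A: {radius: 2.64, class: aliphatic}
    D2A: {radius: 2.64, class: aliphatic}
    D3A: {radius: 2.64, class: aliphatic}
    C4A: {radius: 2.64, class: aliphatic}
    D1B: {radius: 2.64, class: aliphatic}
    D2B: {radius: 2.64, class: aliphatic}
    D3B: {radius: 2.64, class: aliphatic}
    C4B: {radius: 2.64, class: aliphatic}
  tails: [D1A, D2A, D3A, C4A, D1B, D2B, D3B, C4B]
CHOL:
  anchor: ROH
  reference: ROH
  beads:
    ROH: {radius: 2.30, class: polar}
    R1: {radius: 2.64, class: aliphatic}
    R2: {radius: 2.64, class: aliphatic}
    R3: {radius: 2.64, class: aliphatic}
    R4: {radius: 2.64, class: aliphatic}
    R5: {radius: 2.64, class: aliphatic}
    C1: {radius: 2.64, class: aliphatic}
    C2: {radius: 2.30, class: aliphatic}
  tails: [C1, C2]
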