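# Synthetic stand-in reference definition (hdv-like construct).
# The sequence is a constructed placeholder, not the published construct;
# length, region inventory, stem sizes and catalytic numbering follow the
# published description.
# P4 is the 14 bp stem; T1 the 2 bp pseudoknot.
name: hdv_synthetic
sequence: GGUGUCCUCGCAGAAAGCGUGCUAGAACACCAGCUUGUGCCACGUGUGGGCUUCCCACACGUGGCACUCGCCACCGUGUGGCGAAAU
leader: UCCUGAGAGCAC
structure: "(((((...(((.....))).[[....))))).]]..((((((((((((((...)))))))))))))).((((((...))))))...."
regions:
  - P1
  - P3
  - T1
  - P4
  - P2
catalytic:
  - 74
display_offset: 1
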