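# Synthetic stand-in reference definition (hammerhead-like construct).
# The sequence is a constructed placeholder, not the published construct;
# length, region inventory, stem sizes and catalytic numbering follow the
# published description.
# G25 and G39 catalytic. The published construct also has a catalytic -1C; it lies in the leader, outside the 0-based ribozyme frame, and is therefore not listed here.
name: hammerhead_synthetic
sequence: GACCAAAGAACCAGCUUGGUCCAGGGGCGUUACCGUUGGGAACGC
leader: GUGCGAUCACAC
structure: "(((((...........))))).....(((((.........)))))"
regions:
  - P1
  - P2
catalytic:
  - 24
  - 38
display_offset: 1
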