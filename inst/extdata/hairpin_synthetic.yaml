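# Synthetic stand-in reference definition (hairpin-like construct).
# The sequence is a constructed placeholder, not the published construct;
# length, region inventory, stem sizes and catalytic numbering follow the
# published description.
# G29 and A59 catalytic; loop B (3' tail) left unannotated.
name: hairpin_synthetic
sequence: CAGUUCUUGCCAUCCCUGCCCUGGCGCAGCGCCCAGCGGGCGGAACUGUUCUUAUUCGAAAACCCAGAUGA
leader: AUAGUAGAUAUG
structure: "((((((..((((.........))))....(((((...)))))))))))......................."
regions:
  - P1
  - P2
  - P3
catalytic:
  - 28
  - 58
display_offset: 1
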