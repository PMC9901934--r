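# Synthetic stand-in reference definition (twister-like construct).
# The sequence is a constructed placeholder, not the published construct;
# length, region inventory, stem sizes and catalytic numbering follow the
# published description.
# General acid A1 (position 0) and general base G39 (position 38).
name: twister_synthetic
sequence: AGUGCGCACCCCAGUGUCGCAAGCCCGACUCACGGGCGGACGGGUUAU
leader: AUGGCGUCGCUC
structure: "..((((.[[[[.[[[..)))).((((.]]]...))))....]]]]..."
regions:
  - P2
  - T1
  - T2
  - P4
catalytic:
  - 0
  - 38
display_offset: 1
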