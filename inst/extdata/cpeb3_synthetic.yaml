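# Synthetic stand-in reference definition (cpeb3-like construct).
# The sequence is a constructed placeholder, not the published construct;
# length, region inventory, stem sizes and catalytic numbering follow the
# published description.
# T1 is the single non-canonical U:U pseudoknot pair.
name: cpeb3_synthetic
sequence: GGGAUAGUAGCUCACGAGUACUCUGAGCUUCACUAUCCCCCACUCUUAUCGACGCACACAGCGUCCACU
leader: AUAAUUAUGCGA
structure: "((((((..(((((..((([.))).)))))....))))))......]....(((((.....)))))...."
regions:
  - P1
  - P2
  - P3
  - T1
  - P4
catalytic:
  - 56
display_offset: 1
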