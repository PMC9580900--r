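# plasmidkit recombination prototypes (synthetic demonstration sites; the
# arm/core sequences are invented, not natural att sequences).
# Strand exchange happens at the start of each site's core; all sites of a
# prototype family share the same core so crossovers are seamless.
# A fragment slot lists its ordered site pair and whether it contributes
# the region between the sites (inner) or outside them (outer).  The
# products map renames the hybrid site formed where the slot ending with
# site X joins the slot starting with site Y ("X+Y").
sites:
  attB1: {sequence: GGGGACAAGTTGTACAACTGGCA, core_start: 10, core_end: 17}
  attP1: {sequence: AAATAATGTTGTACAAGCCCTA, core_start: 9, core_end: 16}
  attL1: {sequence: AAATAATGTTGTACAACTGGCA, core_start: 9, core_end: 16}
  attR1: {sequence: GGGGACAAGTTGTACAAGCCCTA, core_start: 10, core_end: 17}
  attB2: {sequence: GGGGACCACTTGTACAACTGGTA, core_start: 10, core_end: 17}
  attP2: {sequence: AAATGTTGTTGTACAAGCGGTA, core_start: 9, core_end: 16}
  attL2: {sequence: GGGGACCACTTGTACAAGCGGTA, core_start: 10, core_end: 17}
  attR2: {sequence: AAATGTTGTTGTACAACTGGTA, core_start: 9, core_end: 16}
reactions:
  "BP(1-2)":
    fragments:
      - {sites: [attB1, attB2], take: inner}
      - {sites: [attP1, attP2], take: outer}
    products:
      "attB2+attP2": attL2
      "attP1+attB1": attL1
  "LR(1-2)":
    fragments:
      - {sites: [attL1, attL2], take: inner}
      - {sites: [attR1, attR2], take: outer}
    products:
      "attL2+attR2": attB2
      "attR1+attL1": attB1
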