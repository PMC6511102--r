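# Default domain boundaries for human syntaxin-1B (288 aa).
# NON-AUTHORITATIVE: taken from standard protein annotation (UniProt
# P61266; Habc helix bounds by homology with syntaxin-1A). Replace with
# your own boundaries and cite the map used in any region-level result.
protein_length: 288
domains:
  - {name: Ha, start: 28, end: 62}
  - {name: Hb, start: 73, end: 106}
  - {name: Hc, start: 112, end: 144}
  - {name: linker, start: 145, end: 191}
  - {name: SNARE, start: 192, end: 254}
  - {name: TMR, start: 266, end: 288}
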