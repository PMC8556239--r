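# Division of the lumped historical "hay" area (1960-1986) of former
# Czechoslovakia between the green-legume and other green-harvest codes in
# proportion to their 1987 areas.
rules:
  - kind: proportional_split
    country: CSK
    variable: hay
    components: [G2100, G2900, G9000]
    reference_year: 1987
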