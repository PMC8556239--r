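# Division of the lumped historical "hay" area (1960-1986) of Poland into
# green-fodder crop codes, with fixed proportions: 29% temporary grassland,
# 6% lucerne, 42% other green legumes, and the remaining 23% other plants
# harvested green.
rules:
  - kind: proportional_split
    country: POL
    variable: hay
    components: [G1000, G2100, G2900, G9000]
    shares:
      G1000: 0.29
      G2100: 0.06
      G2900: 0.42
      G9000: 0.23
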