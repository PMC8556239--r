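# Country lists and parameters for the fertilizer-allocation stage.
# zero_pg: countries with zero or negligible synthetic N rates on permanent
# grassland (share to cropland is 1 for all years).
# k: the temporary/permanent grassland rate multiplier used when survey data
# distinguish only total grassland from non-grass cropland.
zero_pg: [BGR, HRV, EST, FIN, GRC, HUN, LVA, LTU, PRT, ROU, ESP, SWE]
k:
  DNK: 1.5
  IRL: 2
  DEU: 1
  NLD: 1
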