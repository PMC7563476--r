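# Additional kidney-disease ICD-10 codes used only to EXCLUDE a patient from
# "no known kidney disease": glomerular disease (N00-N08), tubulo-interstitial
# disease and acute kidney failure (N10-N17), other kidney disorders
# (N25-N27), cystic kidney disease (Q61). Applied as the union with the
# Charlson renal set when calling NKD by ICD codes.
name: cdc_kidney_exclusion
match_mode: prefix
codes:
  - N00
  - N01
  - N02
  - N03
  - N04
  - N05
  - N06
  - N07
  - N08
  - N10
  - N11
  - N12
  - N13
  - N14
  - N15
  - N16
  - N17
  - N25
  - N26
  - N27
  - Q61
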