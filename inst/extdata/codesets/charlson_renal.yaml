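# Moderate-to-severe kidney disease, ICD-10 (Quan et al. Charlson mapping).
# Prefix matching on normalized codes (uppercase, dot removed): "N18" matches
# N18, N183, N184, ... Edit freely; the classifier takes any code set.
name: charlson_renal
match_mode: prefix
codes:
  - I120
  - I131
  - N032
  - N033
  - N034
  - N035
  - N036
  - N037
  - N052
  - N053
  - N054
  - N055
  - N056
  - N057
  - N18
  - N19
  - N250
  - Z490
  - Z491
  - Z492
  - Z940
  - Z992
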