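lake_id,has_lepidurus,has_benthic_vegetation
1,TRUE,TRUE
2,FALSE,TRUE
3,TRUE,TRUE
4,FALSE,FALSE
5,TRUE,TRUE
6,FALSE,FALSE
7,TRUE,TRUE
8,FALSE,TRUE
9,TRUE,TRUE
10,FALSE,FALSE
11,TRUE,TRUE
12,FALSE,FALSE
13,TRUE,TRUE
14,FALSE,TRUE
15,TRUE,TRUE
16,FALSE,FALSE
17,TRUE,TRUE
18,FALSE,FALSE
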