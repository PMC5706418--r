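scaffold_type,expert,n_bad,n_pairs
SC,E1,18,165
SC,E2,6,165
SC,E3,8,165
MF,E1,41,135
MF,E2,38,135
MF,E3,33,135
MMF,E1,27,114
MMF,E2,11,114
MMF,E3,9,114
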