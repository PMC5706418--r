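spot,rms_nm
1,109
2,59
3,43.2
4,50.6
5,39
6,13.3
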