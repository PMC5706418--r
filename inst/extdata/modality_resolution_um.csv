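modality,resolution_um
SEM,0.03125
CLSM,0.12
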