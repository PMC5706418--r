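task,n_items,n_no_positive
cell_segmentation,414,15
contact_statistical_A2,414,155
contact_geometrical_A6,414,27
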