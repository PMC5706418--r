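task,expert_pair,ratio
cell_segmentation_combined,E1-E2,0.94
cell_segmentation_combined,E1-E3,0.95
cell_segmentation_combined,E2-E3,0.94
contact_statistical_A2,E1-E2,0.74
contact_statistical_A2,E1-E3,0.75
contact_statistical_A2,E2-E3,0.81
contact_geometrical_A6,E1-E2,0.86
contact_geometrical_A6,E1-E3,0.86
contact_geometrical_A6,E2-E3,0.91
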