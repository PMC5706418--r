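source,algorithm,subset,mean_um,stdev_um,n_points
CLSM,A1,ALL,2.2795,0.6151,32608
CLSM,A1,Internal,2.3075,0.7189,22128
CLSM,A2,ALL,1.1190,0.3128,32608
CLSM,A2,Internal,1.1562,0.3464,22128
CLSM,A4,ALL,2.6851,1.3196,32608
CLSM,A4,Internal,2.7745,1.5440,22128
CLSM,A5,ALL,1.7532,0.3353,32608
CLSM,A5,Internal,1.7648,0.3843,22128
CLSM,A6,ALL,1.1139,0.1960,36249
CLSM,A6,Internal,1.0815,0.2112,25709
CLSM,A7,ALL,1.6251,0.1065,30105
CLSM,A7,Internal,1.6136,0.1175,20064
CLSM,A8,ALL,2.0404,0.3567,32138
CLSM,A8,Internal,2.0674,0.4018,21691
SEM,reference,ALL,1.1242,0.075,104341
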