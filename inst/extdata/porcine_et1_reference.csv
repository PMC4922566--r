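subject_id,optimal_threshold,sensitivity,specificity,accuracy,auc,infarct_volume_ml
1,10.1,0.80,0.74,0.77,0.8333,2.96
2,8.9,0.80,0.86,0.83,0.8908,0.74
3,15.0,0.74,0.70,0.72,0.7650,2.30
4,13.2,0.68,0.72,0.70,0.7528,0.96
5,12.1,0.75,0.69,0.72,0.7750,0.97
6,16.2,0.71,0.75,0.73,0.8110,0.80
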