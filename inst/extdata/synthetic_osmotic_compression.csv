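"pressure_Pa","volumetric_strain"
101.24,0.0174
132.68,0.0184
224.65,0.0354
487.11,0.0776
558.64,0.0898
770.68,0.1256
886.95,0.1387
873.62,0.1397
969.02,0.1608
1052.85,0.1677
1075.12,0.1739
1264.72,0.2049
1488.88,0.2376
1659.16,0.2655
1681.81,0.2683
1697.7,0.2704
1760.6,0.2824
1830.29,0.2873
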