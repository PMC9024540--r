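variable,GLM,GBM,GAM,CTA,ANN,SRE,FDA,RF,MAXENT
bio_01,0.80,0.14,0.66,0.27,0.60,0.48,0.39,0.06,0.69
bio_02,0.59,0.02,0.70,0.00,0.43,0.34,0.02,0.03,0.27
bio_03,0.19,0.08,0.61,0.09,0.16,0.21,0.01,0.05,0.12
bio_07,0.37,0.08,0.65,0.07,0.20,0.19,0.06,0.04,0.29
bio_08,0.09,0.01,0.41,0.02,0.38,0.22,0.26,0.02,0.54
bio_12,0.49,0.02,0.65,0.08,0.59,0.34,0.08,0.02,0.49
bio_14,0.07,0.06,0.55,0.21,0.13,0.23,0.15,0.11,0.30
bio_17,0.54,0.13,0.82,0.64,0.78,0.36,0.25,0.06,0.57
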