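Scenario,EnsembleType,Loss,Absent,Stable,Gain
RCP4.5 2050,Committee averaging,22334,895491,16690,6514
RCP4.5 2070,Committee averaging,34439,898663,4585,3342
RCP8.5 2050,Committee averaging,34801,898511,4223,3494
RCP8.5 2070,Committee averaging,38196,900519,828,1486
RCP4.5 2050,Weighted mean,25408,885378,21537,8706
RCP4.5 2070,Weighted mean,39793,889563,7152,4521
RCP8.5 2050,Weighted mean,38494,889352,8451,4732
RCP8.5 2070,Weighted mean,45560,891102,1385,2982
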