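# Classification counts by criteria-count stratum (<=2, 3, >=4 principal
# criteria), Taiwan validation cohort. correct = called own class.
group,stratum,n,correct,misclassified,indeterminate
KD,le2,14,2,11,1
KD,3,36,16,7,13
KD,ge4,368,361,6,1
FC,le2,158,157,0,1
FC,3,59,56,0,3
FC,ge4,42,10,30,2
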