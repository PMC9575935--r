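# Age-stratified classification counts for the 418 KD patients of the
# Taiwan validation cohort (infants < 1 year vs older).
stratum,n,correct,misclassified,indeterminate
<1y,157,140,10,7
>=1y,261,239,14,8
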