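# Three-way classification counts, Taiwan single-centre blinded validation
# cohort of the two-step KD/FC algorithm (418 KD, 259 FC).
truth,call,count
KD,KD,379
KD,FC,24
KD,INDETERMINATE,15
FC,KD,30
FC,FC,223
FC,INDETERMINATE,6
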