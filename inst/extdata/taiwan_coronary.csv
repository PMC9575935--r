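# Two-step algorithm performance by echocardiographic coronary status among
# the 418 KD patients of the Taiwan validation cohort. The abnormal rows
# (DILATED + ANEURYSM + UNRESOLVED + NO_FOLLOWUP) sum to 52 although the
# source text states 44 abnormal patients with 43 correct; the rows are
# transcribed as printed and the headline 43/44 is handled in code.
status,correct,indeterminate,misclassified
NORMAL,309,10,12
DILATED,30,0,1
ANEURYSM,8,0,0
UNRESOLVED,12,0,0
NO_FOLLOWUP,1,0,0
MISSING,10,0,0
NO_ECHO,9,5,11
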