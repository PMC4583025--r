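sample_id,preparation,condition,replicate
LDM_IgG_1,LDM,IgG,1
LDM_IgG_2,LDM,IgG,2
LDM_basal_1,LDM,basal,1
LDM_basal_2,LDM,basal,2
LDM_insulin_1,LDM,insulin,1
LDM_insulin_2,LDM,insulin,2
pHS_IgG_1,pHS,IgG,1
pHS_IgG_2,pHS,IgG,2
pHS_basal_1,pHS,basal,1
pHS_basal_2,pHS,basal,2
pHS_insulin_1,pHS,insulin,1
pHS_insulin_2,pHS,insulin,2
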