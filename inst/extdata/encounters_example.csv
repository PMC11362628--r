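patient_id,t,age,fev1_pp,on_iv,medicaid,cfrd,pa_positive,mrsa_positive
P00001,0,10.5,100,0,0,0,0,0
P00001,60,10.66,98,0,0,0,0,0
P00001,120,10.83,85,0,0,0,0,0
P00002,0,8.2,80,0,1,0,1,0
P00002,90,8.45,78,1,1,0,1,0
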