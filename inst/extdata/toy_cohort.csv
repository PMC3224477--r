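patient_id,time,event
A,1,achieve
A,3,lose
A,5,achieve
A,9,censor
B,2,achieve
B,4,death
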