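patient_id,surgery_date,age,gender,bmi,asa,device
P01,2017-06-01,68,F,31.2,2,wrist
P02,2017-06-08,59,M,28.4,2,clip
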