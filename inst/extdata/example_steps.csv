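patient_id,timestamp,steps
P01,2017-05-18 09:12,5
P01,2017-05-18 09:48,7
P01,2017-05-18 12:05,120
P01,2017-05-18 16:30,340
P01,2017-05-18 20:15,60
P01,2017-06-01 08:00,12
P01,2017-06-01 13:40,4
P01,2017-06-02 01:30,3
P01,2017-06-03 10:00,250
P01,2017-06-03 11:30,300
P01,2017-06-03 14:00,150
P02,2017-05-25 07:45,80
P02,2017-05-25 11:10,40
P02,2017-05-25 15:20,90
P02,2017-05-25 18:05,110
P02,2017-06-10 09:00,30
P02,2017-06-10 12:30,20
P02,2017-06-10 17:45,55
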