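criterion,mean,sd,min,max,range
gt0_steps,0.80,0.17,0.40,1.00,0.60
gt500_steps,0.63,0.22,0.26,1.00,0.74
ge10_hours,0.56,0.25,0.02,0.96,0.94
three_a_day,0.67,0.22,0.05,0.93,0.88
three_of_four,0.67,0.22,0.04,0.93,0.89
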