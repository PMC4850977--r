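attempt,trial_label,self_assessment,total_duration_s
1,Trial 1,2.5,13.85
2,*,3.5,NA
3,Trial 2,3.5,10.71
4,Trial 3,4.5,11.42
5,Trial 4,5,11.23
6,Trial 5,5,10.48
7,Trial 6,5,11.13
8,Trial 7,5,10.71
9,Trial 8,6,10.80
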