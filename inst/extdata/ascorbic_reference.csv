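germination_h,titration_mean,titration_sd,prediction_mean,prediction_sd,n,titration_letter,prediction_letter
0,7.31,0.34,10.48,2.49,3,a,a
24,11.32,0.43,18.51,2.37,3,b,b
48,12.86,0.61,23.40,2.19,3,b,b
72,16.74,0.60,29.85,3.17,3,c,c
96,21.44,0.69,36.43,2.87,3,d,d
120,30.58,2.39,40.97,1.84,3,e,d
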