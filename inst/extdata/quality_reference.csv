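germination_h,water_pct_mean,water_pct_sd,ph_mean,ph_sd,conductivity_mean,conductivity_sd,n,growth_stage,water_letter,ph_letter,conductivity_letter
0,47.94,0.38,6.41,0.01,837,5.57,3,G1,a,a,a
6,55.61,0.36,6.43,0.02,851,2.65,3,G1,b,a,b
12,56.54,0.39,6.41,0.02,899,4.00,3,S1,c,ab,c
18,59.62,0.41,6.30,0.02,910,4.73,3,S1,d,b,d
24,61.61,0.31,6.37,0.03,947,4.58,3,S1,e,bc,e
30,63.86,0.34,6.25,0.03,992,6.08,3,S1,f,d,g
36,64.50,0.31,6.13,0.03,831,6.67,3,S1,g,e,a
42,64.76,0.28,6.17,0.03,1005,7.00,3,S2,h,e,h
48,67.44,0.39,6.33,0.01,1030,6.08,3,S2,i,b,i
54,69.01,0.47,6.07,0.02,981,4.16,3,S2,j,f,f
60,70.86,0.36,6.03,0.03,1201,6.67,3,S2,k,g,l
66,73.69,0.36,5.88,0.03,951,4.16,3,S2,l,h,e
72,75.98,0.39,5.55,0.03,1139,4.58,3,S2,m,i,j
78,78.14,0.46,5.55,0.01,1433,4.36,3,S2,n,i,p
84,79.48,0.31,5.84,0.03,1251,5.20,3,S2,o,h,m
90,80.67,0.37,5.22,0.01,1131,6.51,3,S2,p,k,j
96,81.15,0.33,5.34,0.03,1514,6.43,3,S3,q,j,r
102,82.33,0.44,5.19,0.03,1157,3.06,3,S3,r,k,k
108,83.80,0.46,5.19,0.03,1302,6.51,3,S3,s,k,n
114,83.95,0.33,5.07,0.03,1492,6.03,3,S3,t,l,q
120,85.24,0.44,5.06,0.03,1354,1.73,3,S3,u,l,o
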