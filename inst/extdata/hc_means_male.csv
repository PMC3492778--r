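hc,Eg_mean,Eg_sem,ST_mean,ST_sem,Cam_mean,Cam_sem
total_ng,1577,78,1217,115,1128,91
(Z)-9-C23:1,5.24,0.21,1.12,0.1,1.05,0.08
(Z)-7-C23:1,52.01,1.13,20.42,0.56,14.93,0.47
(Z)-5-C23:1,2.08,0.08,0.88,0.1,0.76,0.05
C23,12.78,0.42,7.77,0.21,8.26,0.24
2-Me-C24,0.94,0.19,0.77,0.09,0.44,0.07
(Z)-9-C25:1,2.62,0.13,5.33,0.18,5.88,0.16
(Z)-7-C25:1,4.08,0.17,34.55,0.87,39.15,0.44
(Z)-5-C25:1,0.05,0.02,1.66,0.09,1.09,0.04
C25,3.09,0.27,4.14,0.18,5.45,0.16
2-Me-C26,7.4,0.44,9.55,0.44,7.02,0.15
C27,2.1,0.32,1.51,0.13,3.46,0.26
2-Me-C28,6.2,0.26,3.88,0.53,4.47,0.29
C29,0.45,0.1,0.66,0.36,0.59,0.09
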