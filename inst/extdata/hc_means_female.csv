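hc,Eg_mean,Eg_sem,ST_mean,ST_sem,Cam_mean,Cam_sem
total_ng,2141,167,2767,210,3044,187
(Z)-9-C23:1,2.1,0.08,0.72,0.1,0.76,0.11
(Z)-7-C23:1,54.83,1.1,30.25,0.63,26.67,1.42
(Z)-5-C23:1,2.12,0.08,1.96,0.06,1.83,0.15
C23,9.97,0.22,8.04,0.16,7.97,0.16
2-Me-C24,0.28,0.05,0.63,0.12,0.45,0.07
(Z)-9-C25:1,2.33,0.08,3.56,0.15,3.87,0.21
(Z)-7-C25:1,3.87,0.28,29.81,0.98,32.6,1.09
(Z)-5-C25:1,0.03,0.01,0.41,0.04,0.59,0.04
C25,3.84,0.28,5.07,0.38,5.28,0.54
2-Me-C26,3.8,0.24,6.36,0.32,6.24,0.17
C27,5.38,0.4,4.46,0.45,4.49,0.74
2-Me-C28,8.89,0.4,4.59,0.26,4.36,0.24
C29,2.68,0.29,2.05,0.44,2.2,0.7
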