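#n0=100
#interval_h=0.5
group,interval_index,deaths
male_pooled,1,0
male_pooled,2,0
male_pooled,3,0
male_pooled,4,0
male_pooled,5,0
male_pooled,6,0
male_pooled,7,2
male_pooled,8,3
male_pooled,9,7
male_pooled,10,5
male_pooled,11,9
male_pooled,12,17
male_pooled,13,14
male_pooled,14,14
male_pooled,15,13
male_pooled,16,8
male_pooled,17,3
male_pooled,18,2
male_pooled,19,2
male_pooled,20,1
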