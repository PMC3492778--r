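#replicates=112
#no_mating=12
design,strain_female,strain_male,count
male_choice,ST,ST,32
male_choice,ST,Cam,22
male_choice,Cam,ST,18
male_choice,Cam,Cam,28
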