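#replicates=142
#no_mating=29
design,strain_female,strain_male,count
female_choice,Eg,Eg,36
female_choice,Eg,Cam,19
female_choice,Cam,Eg,15
female_choice,Cam,Cam,43
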