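#replicates=108
#no_mating=8
design,strain_female,strain_male,count
male_choice,Eg,Eg,17
male_choice,Eg,Cam,23
male_choice,Cam,Eg,33
male_choice,Cam,Cam,27
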