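#replicates=53
#no_mating=2
design,strain_female,strain_male,count
multiple_choice,Eg,Eg,12
multiple_choice,Eg,Cam,8
multiple_choice,Cam,Eg,7
multiple_choice,Cam,Cam,24
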