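#replicates=55
#no_mating=5
design,strain_female,strain_male,count
multiple_choice,ST,ST,11
multiple_choice,ST,Cam,14
multiple_choice,Cam,ST,11
multiple_choice,Cam,Cam,14
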