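#replicates=124
#no_mating=24
design,strain_female,strain_male,count
female_choice,ST,ST,6
female_choice,ST,Cam,44
female_choice,Cam,ST,4
female_choice,Cam,Cam,46
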