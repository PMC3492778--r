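#replicates=127
#no_mating=20
design,strain_female,strain_male,count
female_choice,Eg,Eg,46
female_choice,Eg,ST,9
female_choice,ST,Eg,35
female_choice,ST,ST,17
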