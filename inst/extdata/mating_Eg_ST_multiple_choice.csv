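#replicates=53
#no_mating=0
design,strain_female,strain_male,count
multiple_choice,Eg,Eg,13
multiple_choice,Eg,ST,5
multiple_choice,ST,Eg,13
multiple_choice,ST,ST,22
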