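#replicates=106
#no_mating=6
design,strain_female,strain_male,count
male_choice,Eg,Eg,14
male_choice,Eg,ST,14
male_choice,ST,Eg,36
male_choice,ST,ST,36
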