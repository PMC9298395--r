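status_sex,producers,produced_subgroup,produced_other,members_subgroup,members_other
breeder male,31,109,18,340,155
breeder female,37,66,17,263,199
helper male,12,24,9,392,292
helper female,5,6,0,76,37
independent male,1,1,0,20,27
independent female,0,0,0,0,3
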