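status_sex,non_immigrant,possible_immigrant,immigrant
breeder male,11,21,1
breeder female,31,8,21
helper male,161,7,33
helper female,126,5,21
helper unknown,30,0,3
independent male,7,3,7
independent female,2,0,2
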