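id,population,group,subgroup,status,sex,sl_mm,LocA_1,LocA_2,LocB_1,LocB_2
f1,P1,G1,G1.S1,breeder male,M,55,101,103,202,204
f2,P1,G1,G1.S1,breeder female,F,44,101,105,202,206
o1,P1,G1,G1.S1,offspring,U,12,103,105,0,0
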