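id,population,group,subgroup,status,sex,sl_mm,LocA_1,LocA_2,LocB_1,LocB_2,LocC_1,LocC_2
bm1,P1,G1,G1.S1,breeder male,M,58,101,103,201,203,301,303
bf1,P1,G1,G1.S1,breeder female,F,45,105,107,205,207,305,307
bf2,P1,G1,G1.S2,breeder female,F,42,109,111,209,211,309,311
h1,P1,G1,G1.S1,helper,M,35,101,105,201,205,301,305
h2,P1,G1,G1.S1,helper,F,30,103,107,203,207,303,307
h3,P1,G1,G1.S1,helper,M,25,101,107,203,205,301,307
h4,P1,G1,G1.S2,helper,F,22,101,109,201,209,303,309
h5,P1,G1,G1.S2,helper,M,20,103,111,203,211,301,311
h6,P1,G1,G1.S1,helper,U,28,113,115,213,215,313,315
o1,P1,G1,G1.S1,offspring,U,12,103,105,201,207,303,305
o2,P1,G1,G1.S2,offspring,U,10,101,111,203,209,301,309
i1,P1,G1,G1.S2,independent,M,33,121,123,221,223,321,323
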