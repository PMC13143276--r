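species,region,eye_type,D_um,dphi_deg,L_um,f_um,f_prime_um,F,source
Calliphora vicina,Male acute zone,NS,37,1.07,340,74,99,2,bib49;bib31;bib82;bib83
Calliphora vicina,Female acute zone,NS,29,1.28,280,58,78,2,bib31
Musca domestica,Male love spot,NS,36,1.75,250,72,96,2,bib31;bib47
Musca domestica,Male peripheral,NS,20,3.5,140,40,54,2,bib31
Drosophila melanogaster,Average,NS,16.5,5,83,20,27,1.25,bib49;bib31;bib84
Coenesia attenuata,Female frontal,NS,20,2.3,140,25,28,1.25,bib28
Bibio marci,Male dorsal,NS,33,1.6,230,70,94,2.1,bib110
Bibio marci,Male ventral and female,NS,21,3.7,110,36,48,1.7,bib110
Dilophus febrilis,Male dorsal,NS,24,2.2,180,40,54,1.7,bib110
Dilophus febrilis,Male ventral and female,NS,15,5.1,60,16,21,1.1,bib110
Holcocephela fusca,Acute zone max. acuity,NS,75,0.28,230,160,176,2.53,bib103
Holcocephela fusca,Peripheral,NS,21,3.5,123,33,45,1.6,bib103
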