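species,region,eye_type,D_um,dphi_deg,L_um,f_um,f_prime_um,F,source
Tenodora australasiae,z=15 x=20 (fovea),FUSED,47.5,0.64,500,205,445,8,bib70
Tenodora australasiae,z=15 x=30,FUSED,51.5,0.8,535,335,405,6.5,bib70
Tenodora australasiae,z=15 x=10,FUSED,41,1,415,305,375,7.4,bib70
Tenodora australasiae,z=15 x=0,FUSED,35,1.1,285,205,275,5.9,bib70
Tenodora australasiae,z=15 x=60,FUSED,42,1.6,390,150,212,3.6,bib70
Tenodora australasiae,z=15 x=100,FUSED,33,2.5,330,110,153,3.3,bib70
Sympetrum spp.,Ventral -60,FUSED,31,1.85,461,124,166,4,bib44
Sympetrum spp.,Ventral -5,FUSED,27,1.75,461,108,148,,bib44
Sympetrum spp.,Dorso-ventral border,FUSED,31,1.69,516,124,167,,bib44
Sympetrum spp.,Dorsal +50,FUSED,53,1.82,627,92,123,,bib44
Sympetrum spp.,Dorsal +70,FUSED,61.5,1.78,886,246,330,4,bib44
Sympetrum spp.,Dorsal fovea,FUSED,71,0.35,1107,305,410,4.4,bib44
Apis mellifera drone,Dorsal eye,FUSED,40,1,500,205,275,5.1,bib54
Apis mellifera drone,Top ventral,FUSED,28,2.1,400,145,194,5.1,bib54
Apis mellifera drone,Mid ventral,FUSED,25,2.8,280,82,110,3.3,bib54
Apis mellifera drone,Basal ventral,FUSED,18,4.4,150,54,72,3,bib54
Apis mellifera worker,Max. acuity,FUSED,25,1.6,350,100,134,5.6,bib101;bib40
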