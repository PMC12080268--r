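rank,foldx_variant,foldx_ddg,foldx_ddg_sem,ev_variant,ev_delta_e
1,D138N,-5.35,0.02,Q289G,3.13
2,D138C,-4.34,0.01,V226I,2.63
3,E205M,-4.32,0.08,P111I,2.42
4,D138L,-4.14,0.01,D164A,2.34
5,E20M,-4.04,0.27,A178S,1.97
6,E205C,-4.01,0.01,P111V,1.72
7,D138V,-3.94,0.37,Q289A,1.65
8,E205Q,-3.93,0.06,S180T,1.26
9,E205L,-3.87,0.01,T110N,1.22
10,S280L,-3.78,0.30,N299S,1.18
11,S280M,-3.77,0.01,E81A,1.00
12,D138A,-3.62,0.01,D164G,0.99
13,D138S,-3.60,0.03,T236Q,0.93
14,E20L,-3.36,0.22,V150L,0.87
15,G181R,-3.32,0.24,Y188V,0.70
16,S114D,-3.32,0.01,T236A,0.68
17,D138T,-3.20,0.09,Q239K,0.68
18,E175M,-3.09,0.29,L201K,0.67
19,E205A,-3.05,0.01,S123T,0.67
20,E20I,-2.84,0.25,A153D,0.66
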