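method,variant,tm,tm_sem
FoldX,G181R,84.8,0.1
FoldX,S280L,84.2,0.2
FoldX,S280M,84.1,0.2
FoldX,S114D,82.6,0.1
FoldX,WT,82.2,0.1
FoldX,E205L,80.9,0.1
FoldX,E205C,79.5,0.1
FoldX,E205Q,78.8,0.2
FoldX,E205M,78.5,0.2
FoldX,E205A,78.4,0.2
FoldX,D138A,74.5,0.1
FoldX,D138S,74.4,0.1
FoldX,D138N,74.4,0.4
FoldX,D138T,73.8,0.3
FoldX,D138L,73.3,0.2
FoldX,D138C,73.2,0.1
FoldX,D138V,73.1,0.2
FoldX,E20I,72.6,0.1
FoldX,E20L,70.9,0.1
FoldX,E20M,70.2,0.1
FoldX,E175M,55.3,1.4
EVmutation,Q289G,85.0,0.2
EVmutation,P111I,83.5,0.3
EVmutation,S180T,83.2,0.2
EVmutation,V226I,83.1,0.2
EVmutation,Q289A,82.8,0.2
EVmutation,T236Q,82.8,0.2
EVmutation,S123T,82.8,0.4
EVmutation,V150L,82.8,0.2
EVmutation,A153D,82.8,0.3
EVmutation,T236A,82.7,0.3
EVmutation,Q239K,82.6,0.3
EVmutation,P111V,82.5,0.2
EVmutation,D164G,82.4,0.3
EVmutation,L201K,82.3,0.2
EVmutation,E81A,82.3,0.3
EVmutation,WT,82.2,0.1
EVmutation,D164A,82.1,0.0
EVmutation,T110N,81.7,0.1
EVmutation,Y188V,81.7,0.3
EVmutation,A178S,81.0,0.2
EVmutation,N299S,80.8,0.1
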