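variant,delta_e,tm,tm_sem,reference
S180T/Q289G,4.43,85.9,0.1,FALSE
P111I/Q289G,5.47,85.7,0.3,FALSE
P111V/Q289G,4.81,85.6,0.2,FALSE
V226I/Q289G,5.83,85.4,0.3,FALSE
T236Q/Q289G,4.10,85.3,0.2,FALSE
T110N/Q289G,4.44,85.2,0.1,FALSE
D164A/Q289G,5.41,85.1,0.3,FALSE
D164G/Q289G,4.09,85.1,0.3,FALSE
E81A/Q289G,4.19,85.0,0.2,FALSE
Q289G,3.13,85.0,0.2,TRUE
Q289G/N299S,4.35,84.3,0.2,FALSE
P111V/V226I,4.26,83.8,0.1,FALSE
A178S/Q289G,5.23,83.8,0.2,FALSE
P111I/V226I,5.12,83.7,0.3,FALSE
P111I/Q289A,4.15,83.4,0.3,FALSE
P111I/D164A,4.85,83.2,0.3,FALSE
V226I/Q289A,4.37,83.0,0.2,FALSE
D164A/V226I,5.03,82.8,0.3,FALSE
P111I/A178S,4.49,82.6,0.2,FALSE
WT,0.00,82.2,0.1,TRUE
A178S/V226I,4.55,81.7,0.2,FALSE
D164A/A178S,4.31,81.2,0.1,FALSE
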