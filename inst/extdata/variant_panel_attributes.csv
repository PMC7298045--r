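name,hc_14,hc_20,hc_81,lc_1,epimatrix_hc,epimatrix_lc,fab_tm,tagg,kd_pM
PCa75,R,P,H,A,1.99,-19.3,61.8,61.5,247.0
PCa46,P,L,Q,A,-44.3,-19.3,68.3,70.5,279.2
PCa47,P,L,H,A,-8.9,-19.3,68.1,70.2,284.5
PCa50,R,L,Q,A,-29.6,-19.3,66.2,67.8,281.6
PCa51,R,L,H,A,5.75,-19.3,65.9,68.0,298.6
PCa60,R,L,Q,A,-29.6,-33.6,69.7,72.3,323.9
PCa62,P,L,Q,D,-44.3,-33.6,69.4,75.7,323.3
PCa63,P,L,H,D,-8.93,-33.6,69.6,75.6,325.3
PCa64,P,P,Q,D,-37.3,-33.6,68.2,70.0,372.3
PCa65,P,P,H,D,-2.02,-33.6,68.5,70.0,405.8
PCa66,R,L,Q,D,-29.6,-33.6,69.4,72.2,405.4
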