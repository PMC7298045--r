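name,target_format,heavy_count,light_count
Panitumumab,EGFR; Human IgG2,1,0
Denosumab,RANK-L; Human IgG2,0,1
Evolocumab,PCSK9; Human IgG2,4,2
Brodalumab,IL-17R; Human IgG2,0,0
Erenumab,CGRP receptor; Human IgG2,3,1
Nivolumab,PD1; Human IgG4,3,0
Dupilumab,IL-4R alpha; Human IgG4,1,2
Ustekinumab,IL-12/23; Human IgG1,2,3
Canakinumab,IL-1beta; Human IgG1,2,3
Golimumab,TNF; Human IgG1,0,0
Ofatumumab,CD20; Human IgG1,1,0
Ipilimumab,CTLA-4; Human IgG1,1,1
Secukinumab,IL-17a; Human IgG1,1,1
Alirocumab,PCSK9; Human IgG1,2,1
Daratumumab,CD38; Human IgG1,0,0
Olaratumab,PDGFR alpha; Human IgG1,4,0
Bezlotoxumab,C. difficile enterotoxin B; Human IgG1,3,0
Sarilumab,IL-6R; Human IgG1,1,1
Durvalumab,PD-L1; Human IgG1,0,1
Burosumab,FGF23; Human IgG1,1,1
Cemiplimab,PD-1; Human mAb,1,7
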