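protein_id,protein_name,gene,comparison,fc_magnitude,direction,p_adj
ANXA3,Annexin,ANXA3,B_HF,1.37,up,0.01
LOC101123672,NTR domain-containing protein W5NUX8,LOC101123672,B_HF,1.79,up,0.02
RNASET2,Uncharacterized protein W5P4A8,RNASET2,B_HF,2.02,up,0.02
FLNA,Filamin A,FLNA,B_HF,1.35,up,0.02
APOE,Apolipoprotein E,APOE,B_HF,1.45,up,0.02
TLN1,Talin 1,TLN1,B_HF,1.30,up,0.02
CCT4,T-complex protein 1 subunit delta,CCT4,B_HF,1.28,up,0.02
RPS17,Ribosomal protein S17,RPS17,B_HF,1.29,up,0.02
CCT6A,Chaperonin containing TCP1 subunit 6A,CCT6A,B_HF,1.40,up,0.03
CCT6A,Chaperonin containing TCP1 subunit 6A,CCT6A,B_R,1.35,up,0.02
LOC101115576,SERPIN domain-containing protein W5Q0X5,LOC101115576,B_HF,2.92,up,0.03
ARPC3,Actin-related protein 2/3 complex subunit 3,ARPC3,B_HF,1.83,up,0.03
FLNB,Filamin B,FLNB,B_HF,1.34,up,0.03
LOC101119509,SERPIN domain-containing protein W5Q124,LOC101119509,B_HF,3.58,up,0.03
ITGB1,Integrin beta,ITGB1,B_HF,1.21,up,0.03
LOC101113728,Clusterin,LOC101113728,B_HF,1.93,up,0.03
TPP1,Tripeptidyl peptidase 1,TPP1,B_HF,1.46,up,0.03
TCP1,T-complex protein 1 subunit alpha,TCP1,B_HF,1.26,up,0.03
HSP90B1,Heat shock protein 90 beta family member 1,HSP90B1,B_HF,1.38,up,0.04
GM2A,GM2 ganglioside activator,GM2A,B_HF,2.05,up,0.04
CCT8,T-complex protein 1 subunit theta,CCT8,B_HF,1.20,up,0.05
TXNDC17,Thioredoxin domain containing 17,TXNDC17,B_HF,1.22,up,0.05
GC,GC vitamin D binding protein,GC,B_HF,1.94,up,0.05
CCT3,T-complex protein 1 subunit gamma,CCT3,B_HF,1.29,up,0.05
PFN1,Profilin,PFN1,B_R,1.21,up,0.02
ACSM1,Acyl-CoA synthetase medium chain family member 1,ACSM1,B_R,1.48,up,0.02
HAGH,Hydroxyacylglutathione hydrolase,HAGH,B_HF,1.60,down,0.01
HAGH,Hydroxyacylglutathione hydrolase,HAGH,B_R,1.54,down,0.01
APOA4,Apolipoprotein A4,APOA4,B_HF,2.61,down,0.01
APOA4,Apolipoprotein A4,APOA4,HF_R,2.36,up,0.004
CRYZ,Crystallin zeta,CRYZ,B_HF,1.24,down,0.01
PTER,Phosphotriesterase related,PTER,B_HF,1.97,down,0.02
APOA2,Apolipoprotein A2,APOA2,B_HF,1.86,down,0.02
FMO3,Dimethylaniline monooxygenase [N-oxide-forming],FMO3,B_HF,1.78,down,0.02
LOC101111664,Glutathione transferase,LOC101111664,B_HF,1.72,down,0.02
SLC27A2,Solute carrier family 27 member 2,SLC27A2,B_HF,1.37,down,0.02
LOC101109111,Aldo_ket_red domain-containing protein,LOC101109111,B_HF,2.33,down,0.02
TST,Sulfurtransferase,TST,B_HF,1.50,down,0.02
LOC101114319,Uncharacterized protein W5NYA7,LOC101114319,B_HF,1.38,down,0.03
SLC5A12,Solute carrier family 5 member 12,SLC5A12,B_HF,1.36,down,0.03
W5Q8A9,Acyl-CoA_dh_1 domain-containing protein W5Q8A9,,B_HF,1.37,down,0.03
DHRS1,Dehydrogenase/reductase 1,DHRS1,B_HF,1.33,down,0.03
UPP2,Uridine phosphorylase,UPP2,B_HF,1.98,down,0.03
W5PN31,Uncharacterized protein W5PN31,,B_HF,1.33,down,0.03
PRDX1,Peroxiredoxin,PRDX1,B_HF,1.29,down,0.03
BDH1,3-hydroxybutyrate dehydrogenase 1,BDH1,B_HF,1.40,down,0.05
ACSM5,Acyl-CoA synthetase medium chain family member 5,ACSM5,B_R,2.15,down,0.01
PDXK,Pyridoxal kinase,PDXK,B_R,1.25,down,0.02
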