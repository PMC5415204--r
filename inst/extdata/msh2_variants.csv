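variant,ddg,solvent_accessibility,half_life_h,half_life_sd,nuclear,msh6_interaction,patient_found,temperature_sensitivity
WT,0.0,NA,19,3,yes,yes,FALSE,none
R39E,3.4,17.4,4,2,yes,yes,FALSE,ts
A54Y,21.2,0.0,8,0.1,yes,yes,FALSE,ts
L75K,3.0,6.1,5,2,yes,yes,FALSE,ts
Y98C,2.5,19.8,13,2,yes,yes,TRUE,ts_weak
L135Y,3.4,16.2,22,4,yes,yes,FALSE,none
D180F,16.5,0.1,6,1,yes,yes,TRUE,none
L187P,8.8,0.7,5,1,yes,no,TRUE,none
C199R,5.5,0.0,5,1,partial,no,TRUE,none
K228E,0.2,100,20,1,yes,yes,FALSE,none
M253Y,-0.1,94.4,20,2,yes,yes,FALSE,none
A266W,39.7,0.0,4,0.4,yes,weak,FALSE,none
D283K,0.5,100,8,1,yes,yes,FALSE,none
C333Y,21.7,0.3,5,0.4,partial,weak,TRUE,none
A399K,9.4,0.3,11,1,yes,yes,FALSE,none
D459I,2.4,20.6,13,1,yes,yes,FALSE,none
E561V,0.0,78,20,5,yes,yes,FALSE,none
D603N,1.0,3.8,6,2,partial,yes,TRUE,none
P622T,3.7,0.0,10,2,partial,yes,TRUE,cs
A649F,-0.3,100,16,3,yes,yes,FALSE,none
G669D,12.7,10.3,7,1,yes,yes,TRUE,none
G683R,9.8,0.0,7,3,partial,no,TRUE,none
P696F,13.8,0.0,4,1,yes,weak,FALSE,none
S743P,7.5,0.0,7,4,yes,yes,FALSE,none
L851P,5.1,35.3,16,1,yes,yes,FALSE,none
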