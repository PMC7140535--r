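entity,initial_count_per_uL,half_life_value,half_life_unit
B,260,3.3,days
TH,876,3.3,days
TC,434,3.3,days
CDC,351,3.3,days
M,351,3.3,days
P,0,3.3,days
IC,0,4.0,days
ODC,45000,4.0,days
IFN-G,0,1.6,days
IL-2,0,1.6,days
IL-4,0,1.6,days
IL-10,0,1.6,days
IL-12,0,1.6,days
IL-17,0,1.6,days
IL-23,0,1.6,days
TGFB,0,1.6,days
MBP,0,3,days
IgG,0,23.0,days
Chemokine,0,3.0,hours
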