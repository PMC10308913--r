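id,name,formula
glc[c],glucose,C6H12O6
g6p[c],glucose-6-phosphate,C6H13O9P
f6p[c],fructose-6-phosphate,C6H13O9P
fbp[c],fructose-16-bisphosphate,C6H14O12P2
dhap[c],dihydroxyacetone phosphate,C3H7O6P
gap[c],glyceraldehyde-3-phosphate,C3H7O6P
bpg13[c],13-bisphosphoglycerate,C3H8O10P2
pg3[c],3-phosphoglycerate,C3H7O7P
pg2[c],2-phosphoglycerate,C3H7O7P
pep[c],phosphoenolpyruvate,C3H5O6P
pyr[c],pyruvate,C3H4O3
accoa[c],acetyl-CoA,C23H38N7O17P3S
coa[c],coenzyme A,C21H36N7O16P3S
oaa[c],oxaloacetate,C4H4O5
mal[c],malate,C4H6O5
fum[c],fumarate,C4H4O4
succ[c],succinate,C4H6O4
ac[c],acetate,C2H4O2
actp[c],acetyl phosphate,C2H5O5P
for[c],formate,CH2O2
glc1p[c],glucose-1-phosphate,C6H13O9P
adpglc[c],ADP-glucose,C16H25N5O15P2
glucan[c],14-alpha-D-glucan (5 glucose units),C30H52O26
glycogen[c],glycogen (6 glucose units),C36H62O31
nh4[c],ammonium,H4N
glu[c],glutamate,C5H9NO4
akg[c],2-oxoglutarate,C5H6O5
nad[c],NAD,C21H27N7O14P2
nadh[c],NADH,C21H28N7O14P2
adp[c],ADP,C10H15N5O10P2
atp[c],ATP,C10H16N5O13P3
pi[c],phosphate,HO4P
ppi[c],pyrophosphate,H4O7P2
co2[c],carbon dioxide,CO2
cellb[c],cellobiose,C12H22O11
cdx[c],cellodextrin (DP4),C24H42O21
glucose[e],glucose,C6H12O6
cellobiose[e],cellobiose,C12H22O11
cellulose[e],cellulose (4 anhydroglucose units),C24H40O20
acetate[e],acetate,C2H4O2
succinate[e],succinate,C4H6O4
formate[e],formate,CH2O2
ammonium[e],ammonium,H4N
co2[e],carbon dioxide,CO2
biomass[e],biomass,C3.69H6.76O2.66N0.25S0.010
salts[e],salts (biomass-only pseudo-species),
atp[e],ATP (reduction bookkeeping),C10H16N5O13P3
coa[e],coenzyme A (reduction bookkeeping),C21H36N7O16P3S
ppi[e],pyrophosphate (reduction bookkeeping),H4O7P2
glycogen[e],glycogen (6 glucose units),C36H62O31
h_c[e],proton (cytosolic bookkeeping),H
h_e[e],proton (extracellular),H
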