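# SYNTHETIC reduced fermentation network of a cellulolytic, succinate-producing
# anaerobe (constructed stand-in; not a deposited model). 63 reactions,
# 36 intracellular + 16 extracellular species. Carbon-balanced by construction;
# water and charge are implicit. Companion metabolite formulas:
# reduced_network_synthetic_metabolites.csv
#
# --- substrate uptake and product secretion ---
glc_upt	glucose[e] -> glc[c]	irrev	0	10
glc_upt_sym	glucose[e] + h_e[e] -> glc[c] + h_c[e]	irrev	0	10
cellb_upt	cellobiose[e] -> cellb[c]	irrev	0	10
cellu_upt	cellulose[e] -> cdx[c]	irrev	0	10
ac_sec	ac[c] -> acetate[e]	irrev	0	1000
succ_sec	succ[c] -> succinate[e]	irrev	0	1000
succ_sec_sym	succ[c] -> succinate[e] + h_e[e]	irrev	0	1000
for_sec	for[c] -> formate[e]	irrev	0	1000
for_sec_sym	for[c] -> formate[e] + h_e[e]	irrev	0	1000
nh4_upt	ammonium[e] -> nh4[c]	irrev	0	1000
nh4_upt_sym	ammonium[e] -> nh4[c] + h_e[e]	irrev	0	1000
co2_ex	co2[c] <=> co2[e]	rev	-1000	1000
glyc_sec	glycogen[c] -> glycogen[e]	irrev	0	1000
glyc_upt	glycogen[e] -> glycogen[c]	irrev	0	0
atp_src	atp[e] -> atp[c]	irrev	0	1000
coa_src	coa[e] -> coa[c]	irrev	0	1000
ppi_sec	ppi[c] -> ppi[e]	irrev	0	1000
# --- glycolysis (PPi-dependent phosphofructokinase) ---
hxk	glc[c] + atp[c] -> g6p[c] + adp[c]	irrev	0	1000
pgi	g6p[c] <=> f6p[c]	rev	-1000	1000
pfk_ppi	f6p[c] + ppi[c] -> fbp[c] + pi[c]	irrev	0	1000
fba	fbp[c] <=> dhap[c] + gap[c]	rev	-1000	1000
tpi	dhap[c] <=> gap[c]	rev	-1000	1000
gapdh	gap[c] + nad[c] + pi[c] -> bpg13[c] + nadh[c]	irrev	0	1000
gapn	gap[c] + nad[c] -> pg3[c] + nadh[c]	irrev	0	1000
pgk	bpg13[c] + adp[c] -> pg3[c] + atp[c]	irrev	0	1000
gpm	pg3[c] <=> pg2[c]	rev	-1000	1000
eno	pg2[c] <=> pep[c]	rev	-1000	1000
pyk	pep[c] + adp[c] -> pyr[c] + atp[c]	irrev	0	1000
fbpase	fbp[c] -> f6p[c] + pi[c]	irrev	0	1000
# --- succinate branch (PEP carboxykinase route) ---
ppck	pep[c] + co2[c] + adp[c] -> oaa[c] + atp[c]	irrev	0	1000
pcka	oaa[c] + atp[c] -> pep[c] + co2[c] + adp[c]	irrev	0	1000
pyc	pyr[c] + co2[c] + atp[c] -> oaa[c] + adp[c] + pi[c]	irrev	0	1000
oaadc	oaa[c] -> pyr[c] + co2[c]	irrev	0	1000
mdh	oaa[c] + nadh[c] -> mal[c] + nad[c]	irrev	0	1000
mdh_rev	mal[c] + nad[c] -> oaa[c] + nadh[c]	irrev	0	1000
malic	mal[c] + nad[c] -> pyr[c] + co2[c] + nadh[c]	irrev	0	1000
fumh	mal[c] <=> fum[c]	rev	-1000	1000
frd	fum[c] + nadh[c] -> succ[c] + nad[c]	irrev	0	1000
frd2	fum[c] + nadh[c] -> succ[c] + nad[c] + h_e[e]	irrev	0	1000
# --- acetate / formate branch ---
pfl	pyr[c] + coa[c] -> accoa[c] + for[c]	irrev	0	1000
pta	accoa[c] + pi[c] -> actp[c] + coa[c]	irrev	0	1000
ack	actp[c] + adp[c] -> ac[c] + atp[c]	irrev	0	1000
ack_rev	ac[c] + atp[c] -> actp[c] + adp[c]	irrev	0	1000
acs	ac[c] + atp[c] + coa[c] -> accoa[c] + adp[c] + pi[c]	irrev	0	1000
# --- glycogen cycle (six glucose units per glycogen, five per glucan) ---
pgm	g6p[c] <=> glc1p[c]	rev	-1000	1000
glgc	glc1p[c] + atp[c] -> adpglc[c] + ppi[c]	irrev	0	1000
glga	adpglc[c] + glucan[c] -> glycogen[c] + adp[c]	irrev	0	1000
glucan_balance	5 glc1p[c] -> 5 pi[c] + glucan[c]	irrev	0	1000
glgp	glycogen[c] + pi[c] -> glc1p[c] + glucan[c]	irrev	0	1000
glgx	glucan[c] + pi[c] -> glc1p[c] + cdx[c]	irrev	0	1000
glucan_hydro	glucan[c] -> glc[c] + cdx[c]	irrev	0	1000
malq	2 glucan[c] -> glycogen[c] + cdx[c]	irrev	0	1000
# --- cellodextrin and cellobiose utilization ---
cbp	cellb[c] + pi[c] -> glc[c] + glc1p[c]	irrev	0	1000
cdp	cdx[c] + 3 pi[c] -> glc[c] + 3 glc1p[c]	irrev	0	1000
cellobiase	cellb[c] -> 2 glc[c]	irrev	0	1000
cdx_hydro	cdx[c] -> cellb[c] + 2 glc[c]	irrev	0	1000
# --- nitrogen assimilation ---
gdh	nh4[c] + akg[c] + nadh[c] -> glu[c] + nad[c]	irrev	0	1000
gdh_rev	glu[c] + nad[c] -> akg[c] + nh4[c] + nadh[c]	irrev	0	1000
# --- energy / phosphate bookkeeping ---
ppa	ppi[c] -> 2 pi[c]	irrev	0	1000
atp_maint	atp[c] -> adp[c] + pi[c] + h_c[e]	irrev	0	1000
ngam	atp[c] -> adp[c] + pi[c]	irrev	0	1000
atp_synth	adp[c] + pi[c] + h_e[e] -> atp[c]	irrev	0	1000
# --- lumped biomass (C3.69 composition per unit; 0.25 N from glutamate cycle) ---
biomass_lumped	0.2 f6p[c] + 0.43 pyr[c] + 0.25 glu[c] + 0.6 accoa[c] + 2 atp[c] + 0.01 salts[e] -> 1 biomass[e] + 0.25 akg[c] + 0.6 coa[c] + 2 adp[c] + 2.2 pi[c] + 0.3 h_c[e]	irrev	0	1000
@objective	biomass_lumped
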