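# Curated X-island protein-coding changes between the RbMM and RbSS strains
# that are conserved (fixed or nearly fixed) in sympatric field populations
# of An. coluzzii and An. gambiae s.s.; codon strings use the
# lowercase-context / uppercase-substituted-base dialect, ref(M)/alt(S).
pos	m_allele	s_allele	codon_change	protein_change	gene_id
18314527	G	A	gGg/gAg	G74E	AGAP013136
19052774	T	G	aAc/aCc	N25T	AGAP001002
19114172	C	G	gGg/gCg	G232A	AGAP001009
19114460	A	C	Tgg/Ggg	W160G	AGAP001009
19114646	G	C	Ctg/Gtg	L98V	AGAP001009
19116606	T	C	cAc/cGc	H197R	AGAP013526
19636043	A	G	aAg/aGg	K272R	AGAP001022
19636265	C	T	gCc/gTc	A346V	AGAP001022
19637489	T	C	Tcg/Ccg	S355P	AGAP001022
19714995	C	T	cGc/cAc	R491H	AGAP001025
19815325	A	T	Acg/Tcg	T339S	AGAP001033
20955148	G	A	aCg/aTg	T281M	AGAP001050
21093789	A	C	Ttt/Gtt	F288V	AGAP001052
22104989	T	C	Aat/Gat	N1296D	AGAP001061
22159522	T	C	Atg/Gtg	M514V	AGAP001061
22751398	A	G	Act/Gct	T252A	AGAP001073
23799338	T	A	gaA/gaT	E879D	AGAP013341
23799431	T	G	gaA/gaC	E848D	AGAP013341
23799525	T	G	aAt/aCt	N817T	AGAP013341
23799541	T	G	Att/Ctt	I812L	AGAP013341
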