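# Published per-specimen results for the extinct tetrapodomorph sample:
# harmonic mean canal diameter (um), printed probability of endothermy, and
# inferred status. p_end_printed is kept as printed (variable precision;
# one value originally typeset with a comma decimal is normalised).
# Specimens sharing one collection number are disambiguated with -a/-b.
taxon	specimen_id	hmc_um	p_end_printed	status
†Acanthostega	MNHN-Histos-373	29.171	8.35e-4	Ectothermy
†Acheloma	MNHN-Histos-375	19.801	5.36e-2	Ectothermy
†Cardiocephalus	MNHN-Histos-1890	20.158	4.60e-2	Ectothermy
†Clepsydrops	MNHN-Histos-556-a	16.400	2.07e-1	Ectothermy
†Clepsydrops	MNHN-Histos-556-b	16.888	1.74e-1	Ectothermy
†Diadectes	MNHN-Histos	20.904	3.34e-2	Ectothermy
†Dictybolos	MNHN-Histos	29.215	8.19e-4	Ectothermy
†Dimetrodon	MNHN-Histos-2712	26.778	2.45e-3	Ectothermy
†Dimetrodon	MNHN-Histos-2713	21.363	2.73e-2	Ectothermy
†Dutuitosaurus	MNHN-Histos-384	28.417	1.17e-3	Ectothermy
†Dutuitosaurus	MNHN-Histos-386	20.257	4.41e-2	Ectothermy
†Dutuitosaurus	MNHN-Histos-3060	33.086	1.44e-4	Ectothermy
†Dutuitosaurus	MNHN-Histos-3068	16.312	2.14e-1	Ectothermy
†Ecolsonia	MNHN-Histos-376	33.224	2.12e-4	Ectothermy
†Edaphosaurus	MNHN-Histos-463	20.060	4.8e-2	Ectothermy
†Eryops	MNHN-Histos	25.667	4.03e-3	Ectothermy
†Eusthenopteron	MNHN-Histos-531	20.157	4.60e-2	Ectothermy
†Ichthyostega	MNHN-Histos-a	17.300	1.49e-1	Ectothermy
†Ichthyostega	MNHN-Histos-b	13.559	4.85e-1	Ectothermy
†Labidosaurus	MNHN-Histos-433	25.341	4.66e-3	Ectothermy
†Limnoscelis	MNHN-Histos	25.806	3.79e-3	Ectothermy
†Mycterosaurus	MNHN-Histos-464	18.211	1.04e-1	Ectothermy
†Ophiacodon	MNHN-Histos-459	19.152	7.06e-2	Ectothermy
†Pareiasaurid_indet.	MNHN-Histos	24.920	5.64e-3	Ectothermy
†Peltobatrachus	MNHN-Histos-229	12.136	6.41e-1	Endothermy
†Romeriid_indet.	MNHN-Histos-437	10.246	8.07e-1	Endothermy
†Rutiodon	MNHN-Histos-3028	17.413	1.42e-1	Ectothermy
†Seymouria	MNHN-Histos-2183	20.607	3.79e-2	Ectothermy
†Seymouria	MNHN-Histos-2184	24.190	7.80e-3	Ectothermy
†Sphenacodon	MNHN-Histos-462	23.140	1.25e-2	Ectothermy
†Trematops	MNHN-Histos	20.293	4.34e-2	Ectothermy
†Whatcheeria	FMNR PR 5022	36.005	3.86e-5	Ectothermy
†Whatcheeria	FMNR PR 5021	36.552	3.02e-5	Ectothermy
†Whatcheeria	FMNR PR 5023	31.221	3.32e-4	Ectothermy
†Whatcheeria	FMNR PR 1962	51.183	4.17e-8	Ectothermy
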