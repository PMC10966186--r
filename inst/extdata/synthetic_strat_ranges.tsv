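# SYNTHETIC stand-in stratigraphic ranges (Ma), stage-level approximations
# compiled from general stratigraphic knowledge of these taxa. Not the
# study's supplementary FAD/LAD table, which is not redistributable here.
taxon	fad_ma	lad_ma
†Eusthenopteron	385	372
†Acanthostega	365	359
†Ichthyostega	365	359
†Whatcheeria	347	331
†Eryops	303	272
†Acheloma	290	272
†Trematops	290	272
†Ecolsonia	290	272
†Dutuitosaurus	237	227
†Peltobatrachus	259	252
†Seymouria	295	272
†Cardiocephalus	295	272
†Limnoscelis	304	295
†Diadectes	305	272
†Clepsydrops	313	300
†Ophiacodon	304	272
†Mycterosaurus	290	272
†Edaphosaurus	303	272
†Dimetrodon	295	272
†Sphenacodon	300	290
†Pareiasaurid_indet.	265	252
†Labidosaurus	290	272
†Romeriid_indet.	310	298
†Dictybolos	290	272
†Rutiodon	228	208
Pleurodeles_waltl	0	0
Xenopus_laevis	0	0
Mus_musculus	0	0
Felis_catus	0	0
Bos_taurus	0	0
Zootoca_vivipara	0	0
Python_regius	0	0
Trachemys_scripta	0	0
Crocodylus_niloticus	0	0
Gallus_gallus	0	0
Columba_livia	0	0
Anas_platyrhynchos	0	0
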