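# SYNTHETIC stand-in extant-taxon state table (the published analysis used
# the extant calibration species of the source regression, whose list is in
# non-redistributable supplementary material). States are uncontroversial:
# birds and mammals endothermic, other extant tetrapods ectothermic.
taxon	state
Pleurodeles_waltl	ectothermy
Xenopus_laevis	ectothermy
Mus_musculus	endothermy
Felis_catus	endothermy
Bos_taurus	endothermy
Zootoca_vivipara	ectothermy
Python_regius	ectothermy
Trachemys_scripta	ectothermy
Crocodylus_niloticus	ectothermy
Gallus_gallus	endothermy
Columba_livia	endothermy
Anas_platyrhynchos	endothermy
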