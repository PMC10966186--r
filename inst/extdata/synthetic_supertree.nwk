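(†Eusthenopteron,(†Acanthostega,(†Ichthyostega,(†Whatcheeria,((†Eryops,(((†Acheloma,†Trematops)Trematopidae,†Ecolsonia)Dissorophoidea,((†Dutuitosaurus,†Peltobatrachus)PeltoDutuit,(Pleurodeles_waltl,Xenopus_laevis)Lissamphibia)Stereospondyli)Euskelia)Temnospondyli,(†Seymouria,(†Cardiocephalus,((†Limnoscelis,†Diadectes)Diadectomorpha,((†Clepsydrops,(†Ophiacodon,(†Mycterosaurus,(†Edaphosaurus,((†Dimetrodon,†Sphenacodon)Sphenacodontidae,(Mus_musculus,(Felis_catus,Bos_taurus)Carnivoramorpha)Mammalia)Sphenacodontia)Edaphosauridae)Eupelycosauria)Ophiacodontia)Synapsida,(†Pareiasaurid_indet.,(†Labidosaurus,(†Romeriid_indet.,(†Dictybolos,((Zootoca_vivipara,Python_regius)Lepidosauria,(Trachemys_scripta,(†Rutiodon,(Crocodylus_niloticus,(Gallus_gallus,(Columba_livia,Anas_platyrhynchos)Neognathae)Aves)Archosauria)Archosauromorpha)Archelosauria)Sauria)Neodiapsida)Romeriida)Eureptilia)Sauropsida)Amniota)Cotylosauria)Reptiliomorpha2)Reptiliomorpha)Tetrapoda)Whatcheeriidae2)Stegocephali2)Stegocephali)Tetrapodomorpha;
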