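species,L,T,K,F,R,N
Eleocharis ovata,8,6,4,9,5,6
Carex bohemica,8,6,5,9,4,5
Lindernia procumbens,8,7,5,9,5,6
Elatine hexandra,8,6,2,10,4,4
Elatine triandra,8,6,4,10,5,5
Elatine hydropiper,8,6,4,10,5,5
Elatine alsinastrum,8,7,5,10,7,5
Eleocharis acicularis,8,5,4,10,5,4
Cyperus fuscus,8,7,4,8,6,7
Cyperus michelianus,8,8,4,8,7,7
Cyperus flavescens,8,7,4,8,7,4
Limosella aquatica,8,6,4,9,6,7
Potentilla supina,8,7,6,7,6,7
Coleanthus subtilis,8,6,4,9,4,5
Veronica peregrina,7,6,4,7,6,6
Veronica anagalloides,8,7,5,9,7,7
Myosurus minimus,8,6,4,7,6,6
Riccia cavernosa,8,6,5,9,6,7
Riccia sorocarpa,7,5,4,5,6,5
Bryum ruderale,8,6,4,5,6,5
Bryum dichotomum,8,6,4,5,6,5
Ranunculus sardous,8,6,3,7,6,6
Ranunculus trichophyllus,7,5,4,11,7,5
Ranunculus flammula,7,5,3,8,4,3
Ranunculus repens,6,5,4,7,6,7
Callitriche palustris s. l.,7,5,5,11,5,5
Juncus ranarius,8,6,5,8,7,5
Juncus compressus,8,5,5,7,7,5
Juncus tenageia,8,6,3,8,4,3
Juncus capitatus,8,6,2,7,3,2
Juncus articulatus,8,5,3,8,6,3
Juncus effusus,7,5,3,7,3,4
Juncus bulbosus,8,5,2,9,3,2
Juncus bufonius,7,5,4,7,5,5
Lythrum hyssopifolia,8,7,3,8,7,5
Lythrum portula,7,6,2,8,4,4
Mentha pulegium,8,7,4,7,6,6
Pulicaria vulgaris,8,7,5,7,6,7
Inula britannica,8,6,6,7,7,6
Schoenoplectus supinus,8,8,5,9,7,5
Alisma lanceolatum,8,7,4,10,7,6
Alisma plantago-aquatica,7,6,4,10,6,7
Sagina nodosa,8,5,3,7,6,3
Sagina procumbens,7,5,4,6,5,5
Isolepis setacea,8,6,2,8,4,3
Stellaria alsine,6,5,3,8,4,4
Radiola linoides,8,6,2,7,3,2
Anagallis minima,7,6,3,7,4,3
Anthoceros punctatus s. l.,7,6,3,7,4,4
Phaeoceros laevis,7,6,3,7,4,4
Fossombronia wondraczekii,7,6,3,7,4,4
Illecebrum verticillatum,8,6,2,6,2,2
Spergularia rubra,8,5,4,5,3,4
Gypsophila muralis,8,6,5,6,4,4
Laphangium luteoalbum,8,6,4,7,5,5
Hypericum humifusum,7,6,2,6,3,3
Montia arvensis,7,5,3,7,4,4
Cerastium dubium,8,7,6,8,7,6
Gnaphalium uliginosum,7,6,4,7,4,5
Plantago major subsp. intermedia,8,6,4,7,6,6
Agrostis stolonifera,7,5,4,7,6,6
Rorippa palustris,7,5,4,8,6,7
Persicaria hydropiper,6,6,4,8,5,8
Persicaria lapathifolia s. l.,7,6,4,7,6,8
Persicaria amphibia,7,5,4,10,6,6
Polygonum aviculare s. l.,7,6,4,5,6,6
Bidens tripartitus,7,6,4,8,6,8
Rumex maritimus,8,6,6,8,7,9
Rumex acetosella,8,5,4,4,3,3
Oxybasis rubra,8,6,5,7,7,9
Erigeron canadensis,8,6,4,4,6,5
Mentha arvensis,7,5,4,6,6,6
Stellaria media s. l.,6,5,4,5,7,8
Scleranthus annuus,8,5,4,4,3,4
Spergula arvensis,7,5,4,5,3,5
Setaria pumila,8,7,5,4,5,5
Teesdalia nudicaulis,8,5,2,4,2,2
Arnoseris minima,8,6,2,4,3,2
Digitaria ischaemum,8,6,4,4,4,4
Equisetum arvense,7,5,5,6,6,5
Capsella bursa-pastoris,7,5,4,5,6,6
Atriplex prostrata,8,6,5,6,7,8
Argentina anserina,7,5,5,6,6,7
Holcus lanatus,7,5,3,6,5,5
Veronica arvensis,7,6,4,4,6,5
Dicranella staphylina,7,5,4,6,5,5
Lysimachia nummularia,6,5,4,6,6,6
Poa pratensis,6,5,5,5,6,6
Leontodon saxatilis,8,6,2,5,5,4
Calliergonella cuspidata,7,5,4,7,6,4
Triglochin palustris,8,5,6,8,7,3
Carex secalina,8,6,7,7,8,5
Bolboschoenus maritimus agg.,8,6,5,9,8,6
Xanthium orientale subsp. italicum,8,7,5,6,7,7
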