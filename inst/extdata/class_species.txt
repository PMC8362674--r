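Anagallis minima
Anthoceros punctatus s. l.
Cardamine parviflora
Carex bohemica
Centaurium pulchellum
Cerastium dubium
Coleanthus subtilis
Crassula aquatica
Cyperus fuscus
Cyperus michelianus
Cyperus esculentus
Elatine alsinastrum
Elatine hexandra
Elatine hydropiper
Elatine triandra
Eleocharis acicularis
Eleocharis ovata
Fossombronia wondraczekii
Gnaphalium uliginosum
Gratiola neglecta
Gypsophila muralis
Hypericum humifusum
Illecebrum verticillatum
Isolepis setacea
Juncus bufonius
Juncus capitatus
Juncus ranarius
Juncus tenageia
Laphangium luteoalbum
Limosella aquatica
Lindernia dubia
Lindernia procumbens
Lythrum hyssopifolia
Lythrum portula
Mentha pulegium
Montia arvensis
Myosurus minimus
Phaeoceros laevis
Plantago major subsp. intermedia
Potentilla supina
Pulicaria vulgaris
Cyperus flavescens
Radiola linoides
Ranunculus sardous
Riccia beyrichiana
Riccia bifurca
Riccia canaliculata
Riccia cavernosa
Riccia ciliifera
Riccia crystallina
Riccia duplex
Riccia huebeneriana
Riccia warnstorfii
Riccia glauca
Riccia sorocarpa
Sagina apetala
Sagina nodosa
Schoenoplectus supinus
Spergularia echinosperma
Spergularia rubra
Veronica anagalloides
Veronica catenata
Veronica peregrina
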