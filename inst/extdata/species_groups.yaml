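# Species-group registry for the Isoeto-Nanojuncetea expert system.
# Kinds: TC = total-cover (#TC) group, SC = single-cover (#SC) group,
# SOC = sociological (###) group (present when >= half its members occur).
groups:
  - name: Isoeto-Nanojuncetea
    kind: TC
    members:
      - Anagallis minima
      - Anthoceros punctatus s. l.
      - Cardamine parviflora
      - Carex bohemica
      - Centaurium pulchellum
      - Cerastium dubium
      - Coleanthus subtilis
      - Crassula aquatica
      - Cyperus fuscus
      - Cyperus michelianus
      - Cyperus esculentus
      - Elatine alsinastrum
      - Elatine hexandra
      - Elatine hydropiper
      - Elatine triandra
      - Eleocharis acicularis
      - Eleocharis ovata
      - Fossombronia wondraczekii
      - Gnaphalium uliginosum
      - Gratiola neglecta
      - Gypsophila muralis
      - Hypericum humifusum
      - Illecebrum verticillatum
      - Isolepis setacea
      - Juncus bufonius
      - Juncus capitatus
      - Juncus ranarius
      - Juncus tenageia
      - Laphangium luteoalbum
      - Limosella aquatica
      - Lindernia dubia
      - Lindernia procumbens
      - Lythrum hyssopifolia
      - Lythrum portula
      - Mentha pulegium
      - Montia arvensis
      - Myosurus minimus
      - Phaeoceros laevis
      - Plantago major subsp. intermedia
      - Potentilla supina
      - Pulicaria vulgaris
      - Cyperus flavescens
      - Radiola linoides
      - Ranunculus sardous
      - Riccia beyrichiana
      - Riccia bifurca
      - Riccia canaliculata
      - Riccia cavernosa
      - Riccia ciliifera
      - Riccia crystallina
      - Riccia duplex
      - Riccia huebeneriana
      - Riccia warnstorfii
      - Riccia glauca
      - Riccia sorocarpa
      - Sagina apetala
      - Sagina nodosa
      - Schoenoplectus supinus
      - Spergularia echinosperma
      - Spergularia rubra
      - Veronica anagalloides
      - Veronica catenata
      - Veronica peregrina
  - name: Eleocharition soloniensis
    kind: TC
    members:
      - Carex bohemica
      - Coleanthus subtilis
      - Crassula aquatica
      - Cyperus fuscus
      - Cyperus michelianus
      - Elatine hexandra
      - Elatine hydropiper
      - Elatine triandra
      - Eleocharis ovata
      - Limosella aquatica
      - Lindernia dubia
      - Lindernia procumbens
      - Potentilla supina
      - Riccia canaliculata
      - Riccia cavernosa
  - name: Radiolion
    kind: TC
    members:
      - Anagallis minima
      - Anthoceros punctatus s. l.
      - Fossombronia wondraczekii
      - Gypsophila muralis
      - Hypericum humifusum
      - Illecebrum verticillatum
      - Isolepis setacea
      - Juncus capitatus
      - Montia arvensis
      - Phaeoceros laevis
      - Radiola linoides
      - Ranunculus sardous
      - Spergularia rubra
  - name: Verbenion
    kind: TC
    members:
      - Elatine alsinastrum
      - Juncus ranarius
      - Lythrum hyssopifolia
      - Mentha pulegium
      - Pulicaria vulgaris
      - Cyperus flavescens
      - Schoenoplectus supinus
  - name: Cyperus fuscus
    kind: SOC
    members:
      - Cyperus fuscus
      - Potentilla supina
      - Limosella aquatica
  - name: Elatine alsinastrum
    kind: SOC
    members:
      - Alisma lanceolatum
      - Elatine alsinastrum
      - Schoenoplectus supinus
  - name: Elatine hexandra
    kind: SOC
    members:
      - Elatine hexandra
      - Elatine triandra
      - Elatine hydropiper
  - name: Eleocharis ovata
    kind: SOC
    members:
      - Carex bohemica
      - Eleocharis ovata
      - Lindernia procumbens
  - name: Myosurus minimus
    kind: SOC
    members:
      - Bryum ruderale
      - Myosurus minimus
      - Ranunculus sardous
  - name: Centunculus minimus
    kind: SOC
    members:
      - Anthoceros punctatus s. l.
      - Anagallis minima
      - Juncus capitatus
      - Radiola linoides
  - name: Gypsophila muralis
    kind: SOC
    members:
      - Gypsophila muralis
      - Laphangium luteoalbum
      - Spergularia rubra
  - name: Isolepis setacea
    kind: SOC
    members:
      - Isolepis setacea
      - Juncus tenageia
      - Stellaria alsine
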