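# RECONSTRUCTED formal-definition set for the Isoeto-Nanojuncetea expert
# system. The structure (class / alliance total-cover conditions; association
# conditions combining the alliance total-cover group with a sociological
# group or a single-species cover threshold) follows the published multilevel
# design; the numeric thresholds are package choices, kept together here so
# they can be edited in one place. Comparators are strict ">" throughout.
syntaxa:
  - name: Isoeto-Nanojuncetea
    rank: class
    formula: TC(Isoeto-Nanojuncetea) > 5
  - name: Eleocharition soloniensis
    rank: alliance
    parent: Isoeto-Nanojuncetea
    cluster: A
    formula: TC(Eleocharition soloniensis) > 10
  - name: Verbenion supinae
    rank: alliance
    parent: Isoeto-Nanojuncetea
    cluster: B
    formula: TC(Verbenion) > 10
  - name: Radiolion linoidis
    rank: alliance
    parent: Isoeto-Nanojuncetea
    cluster: C
    formula: TC(Radiolion) > 10
  - name: Polygono-Eleocharitetum ovatae
    rank: association
    parent: Eleocharition soloniensis
    unit_id: 1
    type: association
    formula: TC(Eleocharition soloniensis) > 10 AND (SOC(Eleocharis ovata)
      OR SOC(Elatine hexandra))
  - name: Cypero fusci-Limoselletum aquaticae
    rank: association
    parent: Eleocharition soloniensis
    unit_id: 2
    type: association
    formula: TC(Eleocharition soloniensis) > 10 AND SOC(Cyperus fuscus)
  - name: Cyperetum micheliani
    rank: association
    parent: Eleocharition soloniensis
    unit_id: 3
    type: association
    formula: TC(Eleocharition soloniensis) > 10 AND COV(Cyperus michelianus) > 25
  - name: Community with Coleanthus subtilis
    rank: association
    parent: Eleocharition soloniensis
    unit_id: 4
    type: community
    formula: TC(Eleocharition soloniensis) > 10 AND COV(Coleanthus subtilis) > 5
  - name: Veronico anagalloidis-Lythretum hyssopifoliae
    rank: association
    parent: Verbenion supinae
    unit_id: 5
    type: association
    formula: TC(Verbenion) > 10 AND COV(Juncus ranarius) > 5
  - name: Cyperetum flavescentis
    rank: association
    parent: Verbenion supinae
    unit_id: 6
    type: association
    formula: TC(Verbenion) > 10 AND COV(Cyperus flavescens) > 25
  - name: Pulicario vulgaris-Menthetum pulegii
    rank: association
    parent: Verbenion supinae
    unit_id: 7
    type: association
    formula: TC(Verbenion) > 10 AND (COV(Pulicaria vulgaris) > 5
      OR COV(Mentha pulegium) > 5)
  - name: Eleocharito-Schoenoplectetum supini
    rank: association
    parent: Verbenion supinae
    unit_id: 8
    type: association
    formula: TC(Verbenion) > 10 AND SOC(Elatine alsinastrum)
  - name: Stellario uliginosae-Isolepidetum setaceae
    rank: association
    parent: Radiolion linoidis
    unit_id: 9
    type: association
    formula: TC(Radiolion) > 10 AND SOC(Isolepis setacea)
  - name: Centunculo minimi-Anthoceretum punctati
    rank: association
    parent: Radiolion linoidis
    unit_id: 10
    type: association
    formula: TC(Radiolion) > 10 AND SOC(Centunculus minimus)
  - name: Hyperico humifusi-Spergularietum rubrae
    rank: association
    parent: Radiolion linoidis
    unit_id: 11
    type: association
    formula: TC(Radiolion) > 10 AND SOC(Gypsophila muralis)
  - name: Panico-Illecebretum verticillati
    rank: association
    parent: Radiolion linoidis
    unit_id: 12
    type: association
    formula: TC(Radiolion) > 10 AND COV(Illecebrum verticillatum) > 5
  - name: Cerastio dubii-Ranunculetum sardoi
    rank: association
    parent: Radiolion linoidis
    unit_id: 13
    type: association
    formula: TC(Radiolion) > 10 AND SOC(Myosurus minimus)
  - name: Community with Montia arvensis
    rank: association
    parent: Radiolion linoidis
    unit_id: 14
    type: community
    formula: TC(Radiolion) > 10 AND COV(Montia arvensis) > 5
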