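# Published releve counts of the reference Isoeto-Nanojuncetea survey:
# database extract classified at the class level, the stratified analysis
# set, counts per classification level, and the per-unit counts of the
# three alliances and 14 units.
totals:
  class_level: 1340
  stratified: 903
  association_level: 541
  class_only: 197
  alliance_only: 157
alliances:
  - { name: Eleocharition soloniensis, cluster: A, releves: 272 }
  - { name: Verbenion supinae, cluster: B, releves: 46 }
  - { name: Radiolion linoidis, cluster: C, releves: 223 }
units:
  - { unit_id: 1, name: Polygono-Eleocharitetum ovatae,
      alliance: Eleocharition soloniensis, cluster: A, type: association,
      releves: 129 }
  - { unit_id: 2, name: Cypero fusci-Limoselletum aquaticae,
      alliance: Eleocharition soloniensis, cluster: A, type: association,
      releves: 127 }
  - { unit_id: 3, name: Cyperetum micheliani,
      alliance: Eleocharition soloniensis, cluster: A, type: association,
      releves: 4 }
  - { unit_id: 4, name: Community with Coleanthus subtilis,
      alliance: Eleocharition soloniensis, cluster: A, type: community,
      releves: 12 }
  - { unit_id: 5, name: Veronico anagalloidis-Lythretum hyssopifoliae,
      alliance: Verbenion supinae, cluster: B, type: association,
      releves: 3 }
  - { unit_id: 6, name: Cyperetum flavescentis,
      alliance: Verbenion supinae, cluster: B, type: association,
      releves: 8 }
  - { unit_id: 7, name: Pulicario vulgaris-Menthetum pulegii,
      alliance: Verbenion supinae, cluster: B, type: association,
      releves: 19 }
  - { unit_id: 8, name: Eleocharito-Schoenoplectetum supini,
      alliance: Verbenion supinae, cluster: B, type: association,
      releves: 16 }
  - { unit_id: 9, name: Stellario uliginosae-Isolepidetum setaceae,
      alliance: Radiolion linoidis, cluster: C, type: association,
      releves: 20 }
  - { unit_id: 10, name: Centunculo minimi-Anthoceretum punctati,
      alliance: Radiolion linoidis, cluster: C, type: association,
      releves: 90 }
  - { unit_id: 11, name: Hyperico humifusi-Spergularietum rubrae,
      alliance: Radiolion linoidis, cluster: C, type: association,
      releves: 42 }
  - { unit_id: 12, name: Panico-Illecebretum verticillati,
      alliance: Radiolion linoidis, cluster: C, type: association,
      releves: 47 }
  - { unit_id: 13, name: Cerastio dubii-Ranunculetum sardoi,
      alliance: Radiolion linoidis, cluster: C, type: association,
      releves: 9 }
  - { unit_id: 14, name: Community with Montia arvensis,
      alliance: Radiolion linoidis, cluster: C, type: community,
      releves: 15 }
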