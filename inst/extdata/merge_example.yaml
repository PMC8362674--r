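# Example taxon merge map: taxonomically critical taxa -> aggregates.
Persicaria lapathifolia subsp. pallida: Persicaria lapathifolia s. l.
Persicaria lapathifolia subsp. lapathifolia: Persicaria lapathifolia s. l.
Callitriche cophocarpa: Callitriche palustris s. l.
Callitriche stagnalis: Callitriche palustris s. l.
Anthoceros agrestis: Anthoceros punctatus s. l.
Anthoceros punctatus: Anthoceros punctatus s. l.
Polygonum aviculare: Polygonum aviculare s. l.
Polygonum arenastrum: Polygonum aviculare s. l.
Stellaria media: Stellaria media s. l.
Galeopsis tetrahit: Galeopsis tetrahit s. l.
Galeopsis bifida: Galeopsis tetrahit s. l.
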