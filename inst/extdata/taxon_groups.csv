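taxon_key,group
Araneae,Arachnida
Arachnida,Arachnida
Formicidae,Insecta
Coleoptera,Insecta
Blattodea,Insecta
Hemiptera,Insecta
Orthoptera,Insecta
Larvae,Insecta
Insecta,Insecta
Chilopoda,Myriapoda
Diplopoda,Myriapoda
Myriapoda,Myriapoda
Isopoda,Crustacea
Oligochaeta,Other
Gastropoda,Other
Invertebrata,Other
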