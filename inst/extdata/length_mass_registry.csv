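taxon_key,a,b,mass_basis,dry_to_fresh_factor,len_min_mm,len_max_mm,fallback_key
Araneae,0.0578,2.113,dry,3.5,0.5,25,Arachnida
Arachnida,0.0500,2.300,dry,3.5,0.5,30,Invertebrata
Formicidae,0.0294,2.480,dry,3.3,0.5,20,Insecta
Coleoptera,0.0312,2.640,dry,3.3,0.5,35,Insecta
Blattodea,0.0246,2.550,dry,3.3,1.0,40,Insecta
Hemiptera,0.0081,2.970,dry,3.3,0.5,25,Insecta
Orthoptera,0.0306,2.550,dry,3.3,1.0,45,Insecta
Larvae,0.0039,2.640,dry,3.9,1.0,40,Insecta
Insecta,0.0305,2.620,dry,3.3,0.5,50,Invertebrata
Chilopoda,0.0149,2.630,dry,3.2,1.0,60,Myriapoda
Diplopoda,0.0507,2.460,dry,3.2,1.0,60,Myriapoda
Myriapoda,0.0300,2.500,dry,3.2,0.5,80,Invertebrata
Isopoda,0.0672,2.540,dry,3.1,0.5,25,Invertebrata
Oligochaeta,0.0020,2.580,dry,5.0,2.0,120,Invertebrata
Gastropoda,0.0546,2.580,dry,5.0,1.0,40,Invertebrata
Invertebrata,0.0281,2.550,dry,3.4,0.1,200,
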