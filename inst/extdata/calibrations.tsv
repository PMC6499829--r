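clade	taxon_a	taxon_b	min	max
Eleutherozoa	Patiria	Holothuria	481	521
Asterozoa	Patiria	Amphipholis	477	521
Echinozoa	Holothuria	Cidaroid_sp	464	470
Holothuroidea	Holothuria	Apostichopus	241	260
Echinoidea	Cidaroid_sp	Strongylocentrotus	269	346.7
Euechinoidea	Strongylocentrotus	Scaphechinus	190.8	235
Irregularia	Scaphechinus	Echinocardium	174	201
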