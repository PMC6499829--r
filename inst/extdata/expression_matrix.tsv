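taxon	alx1	ets1	erg	tbrain	vegfr
Patiria	mesoderm	mesoderm	mesoderm	endomesoderm	absent-in-SM
Amphipholis	SM-specific	SM+NSM	SM+NSM	?	present-in-SM
Ophiuroid_sp	SM-specific	SM+NSM	?	mesoderm	?
Holothuria	SM-specific	SM+NSM	SM+NSM	mesoderm	present-in-SM
Apostichopus	SM-specific	SM+NSM	SM+NSM	mesoderm	present-in-SM
Cidaroid_sp	SM-specific	SM+NSM	SM+NSM	mesoderm	present-in-SM
Camarodont_A	SM-specific	SM+NSM	?	SM-specific	present-in-SM
Camarodont_B	SM-specific	SM+NSM	?	SM-specific	?
Camarodont_C	SM-specific	SM+NSM	?	SM-specific	?
Strongylocentrotus	SM-specific	SM+NSM	SM+NSM	SM-specific	present-in-SM
Scaphechinus	SM-specific	SM+NSM	?	mesoderm	?
Echinocardium	SM-specific	SM+NSM	?	mesoderm	?
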