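((Patiria,(Amphipholis,Ophiuroid_sp)),((Holothuria,Apostichopus),(Cidaroid_sp,((Camarodont_A,(Camarodont_B,(Camarodont_C,Strongylocentrotus))),(Scaphechinus,Echinocardium)))));
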