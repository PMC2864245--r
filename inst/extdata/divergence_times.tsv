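group1	group2	T_myr
Plants	Fungi	1500
Basidiomycetes	Ascomycetes	1200
Homobasidiomycetes	Chytridiomycetes	900
Sordariomycetes	Eurotiomycetes	540
Sordariomycetes	Dothideomycetes	490
Tremellomycetes	Agaricomycetes	700
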