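set	id1	id2	length_aa	identity_pct	rate_printed_e9	ht_flag	group1	group2	T_myr
Pho88	Pho88_Ppatens	Pho88_Spombe	154	26.8	0.420	FALSE	Plants	Fungi	1500
Pho88	Pho88_Ppatens	Pho88_Ccinereus	151	23.1	0.445	FALSE	Plants	Fungi	1500
Pho88	Pho88_Ppatens	Pho88_Pchrysosporium	151	25.0	0.428	FALSE	Plants	Fungi	1500
Pho88	Pho88_Ppatens	Pho88_Cneoformans	152	20.1	0.521	FALSE	Plants	Fungi	1500
Pho88	Pho88_Ccinereus	Pho88_Pchrysosporium	151	64.9	ND	FALSE	Agaricomycetes	Agaricomycetes	NA
Pho88	Pho88_Ccinereus	Pho88_Cneoformans	151	51.3	0.472	FALSE	Agaricomycetes	Tremellomycetes	700
Pho88	Pho88_Pchrysosporium	Pho88_Cneoformans	151	58.6	ND	FALSE	Agaricomycetes	Tremellomycetes	700
uapA	uapA_Ppatens	uapA_Agossypii	466	40.7	0.266	FALSE	Plants	Fungi	1500
uapA	uapA_Ppatens	uapA_Ccinereus	456	38.4	0.288	FALSE	Plants	Fungi	1500
uapA	uapA_Ppatens	uapA_Pchrysosporium	391	43.6	0.263	FALSE	Plants	Fungi	1500
uapA	uapA_Ppatens	uapA_Cneoformans	472	36.9	0.318	FALSE	Plants	Fungi	1500
uapA	uapA_Ccinereus	uapA_Pchrysosporium	391	67.9	ND	FALSE	Agaricomycetes	Agaricomycetes	NA
uapA	uapA_Ccinereus	uapA_Cneoformans	456	39.6	0.560	FALSE	Agaricomycetes	Tremellomycetes	700
uapA	uapA_Pchrysosporium	uapA_Cneoformans	391	43.2	ND	FALSE	Agaricomycetes	Tremellomycetes	700
Tcn1	Tcn1_Cneoformans	Ccchromovir1_Ccinereus	684	53.6	0.441	FALSE	Tremellomycetes	Agaricomycetes	700
Tcn1	Tcn1_Cneoformans	PcMetavir6_Pchrysosporium	684	52.2	ND	FALSE	Tremellomycetes	Agaricomycetes	700
Tcn1	Tcn1_Cneoformans	BatDenTy3-1_Bdendrobatidis	677	49.1	0.381	FALSE	Homobasidiomycetes	Chytridiomycetes	900
Tcn1	PcMetavir6_Pchrysosporium	Ccchromovir1_Ccinereus	688	72.4	ND	FALSE	Agaricomycetes	Agaricomycetes	NA
Tcn1	PcMetavir6_Pchrysosporium	BatDenTy3-1_Bdendrobatidis	677	47.0	0.412	FALSE	Homobasidiomycetes	Chytridiomycetes	900
Tcn1	BatDenTy3-1_Bdendrobatidis	Ccchromovir1_Ccinereus	677	46.5	0.411	FALSE	Homobasidiomycetes	Chytridiomycetes	900
Tcn1	Tcn1_Cneoformans	PpatensLTR1_Ppatens	675	52.0	0.216	TRUE	Fungi	Plants	1500
Tcn1	Tcn1_Cneoformans	SM-Tcn1_Smoellendorffii	682	50.3	0.235	TRUE	Fungi	Plants	1500
Tcn1	PcMetavir6_Pchrysosporium	PpatensLTR1_Ppatens	675	51.8	0.217	TRUE	Fungi	Plants	1500
Tcn1	PcMetavir6_Pchrysosporium	SM-Tcn1_Smoellendorffii	682	49.5	0.230	TRUE	Fungi	Plants	1500
Tcn1	PpatensLTR1_Ppatens	SM-Tcn1_Smoellendorffii	675	58.6	0.429	FALSE	Bryophyta	Lycopodiophyta	NA
Pyggy	PyrTriTy3-2_Ptriticirepentis	NecHaemTy3-4_Nhaematococca	706	77.0	0.259	TRUE	Dothideomycetes	Sordariomycetes	490
Pyggy	PyrTriTy3-2_Ptriticirepentis	ChaGloTy3-8_Cglobosum	706	48.5	0.706	FALSE	Dothideomycetes	Sordariomycetes	490
Pyggy	PyrTriTy3-2_Ptriticirepentis	grh_Mgrisea	701	49.2	0.703	FALSE	Dothideomycetes	Sordariomycetes	490
Pyggy	PyrTriTy3-2_Ptriticirepentis	Dane4_Anidulans	695	55.5	0.531	FALSE	Dothideomycetes	Eurotiomycetes	NA
Pyggy	AltBraTy3-2_Abrassicicola	NecHaemTy3-4_Nhaematococca	709	47.7	0.880	FALSE	Dothideomycetes	Sordariomycetes	490
Pyggy	AltBraTy3-2_Abrassicicola	Dane4_Anidulans	695	49.2	0.649	FALSE	Dothideomycetes	Eurotiomycetes	NA
Pyggy	grh_Mgrisea	Dane4_Anidulans	695	48.5	0.670	FALSE	Sordariomycetes	Eurotiomycetes	540
Pyret	skippy_Foxysporum	PyrTriTy3-1_Ptriticirepentis	648	40.4	0.772	FALSE	Sordariomycetes	Dothideomycetes	490
Pyret	skippy_Foxysporum	AFLAV_Aflavus	673	41.4	0.766	FALSE	Sordariomycetes	Eurotiomycetes	540
Pyret	AFLAV_Aflavus	PyrTriTy3-1_Ptriticirepentis	648	44.3	0.656	FALSE	Eurotiomycetes	Dothideomycetes	NA
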