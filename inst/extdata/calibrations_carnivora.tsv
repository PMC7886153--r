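name	taxa	max	distribution	min
Ferae	Canis_lupus,Manis_javanica	85	N	65
Canidae_Canis_Cuon_Lycaon	Canis_lupus,Cuon_alpinus,Lycaon_pictus	12	U/L	6
Canidae_Vulpes_Nyctereutes	Vulpes_vulpes,Nyctereutes_procyonoides	34	U/L	9
Ursidae	Ailuropoda_melanoleuca,Ursus_arctos	34	U/L	11
Ursidae_Arctotherium_Tremarctos	Arctotherium_sp,Tremarctos_ornatus	10	U/L	3
Ursus_maritimus_Svalbard_tip	Ursus_maritimus_GU573488	0.13	N	0.11
Pinnipedia	Odobenus_rosmarus,Phoca_vitulina	34	U/L	19
Otarioidea	Odobenus_rosmarus,Otaria_byronia	23	U/L	15
Phocidae	Monachus_monachus,Phoca_vitulina	23	U/L	12
Mustelidae_Guloninae_Mustelinae	Gulo_gulo,Mustela_nivalis	27.6	U/L	16.3
Mustelidae_Lutrinae_Ictonychinae	Lutra_lutra,Ictonyx_striatus	27.6	U/L	12.2
Feloidea	Felis_catus,Prionodon_linsang	34	U/L	20
Felidae	Felis_catus,Panthera_leo	20	U/L	14
Felidae_Acinonyx_Puma	Acinonyx_jubatus,Puma_concolor	14	U/L	3.4
Felidae_Leptailurus_Profelis	Leptailurus_serval,Profelis_aurata	14	U/L	4
Felidae_Caracal_Profelis	Caracal_caracal,Profelis_aurata	14	U/L	4
Felidae_Panthera_Neofelis	Panthera_leo,Neofelis_nebulosa	14	U/L	5.95
Viverridae_Genettinae_Viverrinae	Genetta_genetta,Viverra_zibetha	34	U/L	14
Herpestidae_Eupleridae	Herpestes_ichneumon,Eupleres_goudotii	34	U/L	20.5
Herpestidae_Helogale_Crossarchus	Helogale_parvula,Crossarchus_obscurus	20.5	U/L	6
Herpestidae_Galerella_Cynictis	Galerella_sanguinea,Cynictis_penicillata	20.5	U/L	7.4
Hyaenidae_Hyaena_Parahyaena	Hyaena_hyaena,Parahyaena_brunnea	9.5	U/L	3.6
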