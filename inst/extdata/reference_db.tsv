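name	formula	adduct	mz_measured	mz_theoretical	ref_mt_min	delta_mt_pct	delta_printed	mtmz_match	msms_support
Spermidine	C7H19N3	M+H	146.1648	146.1652	8.5	1.6	0.4	TRUE	TRUE
Putrescine	C4H12N2	M+H	89.1072	89.1073	9.1	-0.9	0.1	TRUE	FALSE
Choline	C5H14NO	M	104.1068	104.1070	15.3	-1.8	0.2	FALSE	TRUE
S-adenosylmethionine	C15H22N6O5S	M+H	399.1447	399.1445	16.3	-2.7	-0.2	TRUE	TRUE
Ornithine	C5H12N2O2	M+H	133.0973	133.0972	16.4	-1.3	-0.1	TRUE	TRUE
Sarcosine	C3H7NO2	M+H	90.0550	90.0550	16.6	-1.6	0.0	TRUE	FALSE
Lysine	C6H14N2O2	M+H	147.1128	147.1128	16.6	-1.5	0.0	TRUE	TRUE
Arginine	C6H14N4O2	M+H	175.1190	175.1190	17.2	-1.2	0.0	TRUE	TRUE
Homolysine	C7H16N2O2	M+H	161.1286	161.1285	17.3	-1.1	-0.1	TRUE	TRUE
Gamma-aminobutyrate	C4H9NO2	M+H	104.0703	104.0706	17.4	-0.9	0.3	TRUE	TRUE
Histidine	C6H9N3O2	M+H	156.0769	156.0768	17.4	-0.8	-0.1	FALSE	TRUE
Trimethyllysine	C9H21N2O2	M	189.1607	189.1598	17.8	-2.6	-0.9	TRUE	TRUE
Methylhistidine	C7H11N3O2	M+H	170.0924	170.0924	18.3	-2.3	0.0	TRUE	TRUE
Guanidinopropanoate	C4H9N3O2	M+H	132.0740	132.0768	18.5	-1.9	2.8	TRUE	TRUE
Acetylcholine	C7H16NO2	M	146.1175	146.1176	18.7	-1.6	0.1	TRUE	TRUE
Guanine	C5H5N5O	M+H	152.0570	152.0567	18.7	2.1	-0.3	TRUE	TRUE
Trolamine	C6H15NO3	M+H	150.1126	150.1125	18.8	-0.9	-0.1	TRUE	FALSE
Carnitine	C7H15NO3	M+H	162.1127	162.1125	20.5	-3.9	-0.2	TRUE	TRUE
Pyridoxine	C8H9NO3	M+H	168.0660	168.0655	20.9	-1.3	-2.4	TRUE	TRUE
Acetylcarnitine	C9H17NO4	M+H	204.1233	204.1230	22.3	-1.8	-0.3	TRUE	TRUE
Methylaspartate	C5H9NO4	M+H	148.0606	148.0604	22.3	1.8	-0.2	TRUE	TRUE
Propionylcarnitine	C10H19NO4	M+H	218.1399	218.1387	23.1	-2.3	-1.2	TRUE	TRUE
Glycine	C2H5NO2	M+H	76.0395	76.0393	23.2	-1.7	-0.2	TRUE	FALSE
Creatine	C4H9N3O2	M+H	132.0771	132.0768	23.6	-2.4	-0.3	TRUE	TRUE
Adenosine	C10H13N5O4	M+H	268.1047	268.1040	24.7	-2.4	-0.7	TRUE	FALSE
Alanine	C3H7NO2	M+H	90.0553	90.0550	25.5	0.6	-0.3	TRUE	FALSE
Argininosuccinate	C10H18N4O6	M+H	291.1305	291.1299	27.4	-0.6	-0.6	TRUE	TRUE
Valine	C5H11NO2	M+H	118.0863	118.0863	29.9	1.1	0.0	TRUE	TRUE
Serine	C3H7NO3	M+H	106.0498	106.0499	30.4	-0.2	0.1	TRUE	TRUE
Isoleucine	C6H13NO2	M+H	132.1020	132.1019	30.2	1.2	-0.1	TRUE	FALSE
Leucine	C6H13NO2	M+H	132.1020	132.1019	30.5	1.2	-0.1	TRUE	FALSE
Threonine	C4H9NO3	M+H	120.0654	120.0655	32.5	0.6	0.1	TRUE	TRUE
Asparagine	C4H8N2O3	M+H	133.0610	133.0608	32.6	0.1	-0.2	TRUE	TRUE
Tryptophan	C11H12N2O2	M+H	205.0975	205.0972	33.2	0.5	-0.3	TRUE	TRUE
Methionine	C5H11NO2S	M+H	150.0586	150.0583	33.4	0.7	-0.3	TRUE	TRUE
Glutamine	C5H10N2O3	M+H	147.0767	147.0764	33.5	0.6	-0.3	TRUE	TRUE
Acetylhomoserine	C6H11NO4	M+H	162.0751	162.0761	34.1	0.4	1.0	TRUE	FALSE
Citrulline	C6H13N3O3	M+H	176.1032	176.1030	34.1	0.2	-0.2	TRUE	TRUE
Homocitrulline	C7H15N3O3	M+H	190.1191	190.1186	34.1	0.5	-0.5	TRUE	TRUE
Glutamate	C5H9NO4	M+H	148.0607	148.0604	34.2	0.5	-0.3	TRUE	TRUE
Phenylalanine	C9H11NO2	M+H	166.0867	166.0863	34.9	1.1	-0.4	TRUE	TRUE
Acetyllysine	C8H16N2O3	M+H	189.1237	189.1234	35.3	1.2	-0.3	TRUE	FALSE
Tyrosine	C9H11NO3	M+H	182.0817	182.0812	35.4	1.3	-0.5	TRUE	TRUE
Proline	C5H9NO2	M+H	116.0706	116.0706	36.6	0.6	0.0	TRUE	TRUE
Hypoxanthine	C5H4N4O	M+H	137.0458	137.0458	36.7	-0.8	0.0	TRUE	TRUE
Cysteine	C3H7NO2S	M+H	122.0270	122.0270	37.1	5.0	0.0	TRUE	TRUE
Aspartate	C4H7NO4	M+H	134.0447	134.0448	39.2	1.5	0.1	TRUE	TRUE
Glycine betaine	C5H11NO2	M+H	118.0862	118.0863	40.0	1.4	0.1	TRUE	FALSE
Hydroxyproline	C5H9NO3	M+H	132.0657	132.0655	43.3	1.0	-0.2	TRUE	TRUE
Glutathione	C10H17N3O6S	M+H	308.0924	308.0911	46.7	0.1	-1.3	TRUE	TRUE
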