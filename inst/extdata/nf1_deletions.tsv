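patient_id	proximal_bp	distal_bp	size	microhomology_bp	insertion_seq	insertion_templated	sva_family	snc	mosaic	proximal_location	distal_location	sine_proximal	sine_distal	sine_identity_percent	sine_alignment_bp	mechanism
08D2261	29102848	30079302	976455	-	-	-	-	-	Yes	SUZ12P	between RAB11FIP4 and COPRS	-	-	-	-	NHEJ
100206	29065415	30016354	950940	-	-	-	-	+	Yes	SUZ12P	between RAB11FIP4 and COPRS	-	-	-	-	NHEJ/RBM
D1008345	29094424	30218204	1123781	1	-	-	-	-	No	SUZ12P	UTP6	-	-	-	-	NHEJ
D05.2678	28142439	34112082	5969644	1	-	-	-	-	No	SSH2	MMP28	-	-	-	-	NHEJ
R84329	29074557	30223384	1148828	1	TGTCCCCTCTG	+	-	+	Yes	SUZ12P	UTP6	-	-	-	-	NHEJ/RBM
70969	29092903	30175393	1082491	1	GGCCAGGTT	+	-	-	No	SUZ12P	between RAB11FIP4 and COPRS	-	-	-	-	NHEJ/RBM
619	28946218	31954580	3008363	2	GTAGCAGAAT	+	-	-	No	NF1REPa	ASIC2	-	-	-	-	NHEJ/RBM
61541	29082032	30187273	1105242	2	-	-	-	+	Yes	SUZ12P	between COPRS and UTP6	-	-	-	-	NHEJ/RBM
2535	29101686	30250762	1149077	2	-	-	-	-	No	SUZ12P	between UTP6 and SUZ12	-	-	-	-	NHEJ
R48018	29084006	30241383	1157378	2	-	-	-	-	No	SUZ12P	between UTP6 and SUZ12	-	-	-	-	NHEJ
Ak-47055	29082023	30243011	1160989	4	-	-	-	-	Yes	SUZ12P	between UTP6 and SUZ12	-	-	-	-	NHEJ
D06.1047	29264225	29783515	519291	6	-	-	-	-	Yes	ADAP2	RAB11FIP4	-	-	-	-	MMEJ/RBM
659	28948946	30345260	1396315	20	-	-	-	-	Yes	NF1REPa	NF1REPc	AluY	AluSp	84	135	Alu-mediated NAHR/MMEJ/RBM
1106	29001813	29765892	764080	24	-	-	-	+	No	NF1REPa	RAB11FIP4	AluSz6	FLAM_C	79	112	Alu-mediated NAHR/MMEJ/RBM
D0801587	27726501	29729864	2003364	52	-	-	-	-	Yes	TAOK1	RAB11FIP4	AluY	AluY	89	301	Alu-mediated NAHR/MMEJ/RBM
DA-77	29100005	30101550	1001546	2	-	-	SVA_F1	-	Yes	SUZ12P	between RAB11FIP4 and COPRS	-	-	-	-	SVA insertion
ASB4-55	29103071	29969839	866769	-	-	-	SVA_F	-	Yes	SUZ12P	between RAB11FIP4 and COPRS	-	-	-	-	SVA insertion
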