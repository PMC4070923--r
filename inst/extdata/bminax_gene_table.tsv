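# B. minax (HM776033) mitogenome annotation; coordinates 1-based inclusive,
# J-strand; strand F = majority (J), R = minority (N); genome length 16043 bp.
# trnL2 = trnL(UUR), trnL1 = trnL(CUN), trnS1 = trnS(AGN), trnS2 = trnS(UCN).
gene	strand	start	end	size	kind	anticodon
trnI	F	1	65	65	tRNA	GAT
trnQ	R	66	134	69	tRNA	TTG
trnM	F	145	213	69	tRNA	CAT
nad2	F	213	1235	1023	PCG	.
trnW	F	1244	1311	68	tRNA	TCA
trnC	R	1304	1365	62	tRNA	GCA
trnY	R	1408	1475	68	tRNA	GTA
cox1	F	1474	3009	1536	PCG	.
trnL2	F	3009	3072	64	tRNA	TAA
cox2	F	3078	3764	687	PCG	.
trnK	F	3771	3841	71	tRNA	CTT
trnD	F	3841	3908	68	tRNA	GTC
atp8	F	3909	4070	162	PCG	.
atp6	F	4064	4741	678	PCG	.
cox3	F	4741	5532	792	PCG	.
trnG	F	5539	5604	66	tRNA	TCC
nad3	F	5605	5956	352	PCG	.
trnA	F	5957	6021	65	tRNA	TGC
trnR	F	6027	6090	64	tRNA	TCG
trnN	F	6119	6183	65	tRNA	GTT
trnS1	F	6184	6251	68	tRNA	GCT
trnE	F	6254	6319	66	tRNA	TTC
trnF	R	6338	6403	66	tRNA	GAA
nad5	R	6403	8122	1720	PCG	.
trnH	R	8137	8201	65	tRNA	GTG
nad4	R	8206	9546	1341	PCG	.
nad4l	R	9530	9826	297	PCG	.
trnT	F	9829	9893	65	tRNA	TGT
trnP	R	9894	9959	66	tRNA	TGG
nad6	F	9962	10483	522	PCG	.
cob	F	10483	11619	1137	PCG	.
trnS2	F	11618	11684	67	tRNA	TGA
nad1	R	11701	12640	940	PCG	.
trnL1	R	12651	12716	66	tRNA	TAG
rrnL	R	12717	14049	1333	rRNA	.
trnV	R	14049	14120	72	tRNA	TAC
rrnS	R	14121	14902	782	rRNA	.
CR	F	14903	16043	1141	CR	.
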