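# Gene organization of the Exhippolysmata ensirostris mitogenome,
# GenBank accession MK681888 (16,350 bp, circular), as published.
# Coordinates are 1-based inclusive; Direction + is the heavy strand.
Gene	Direction	Start	End	Anticodon	Start_codon	Stop_codon
nad4	-	13	1239		ATG	TAA
nad4l	-	1323	1577		ATG	TAA
trnT	+	1618	1680	ACA
trnP	-	1686	1748	CCA
nad6	+	1773	2270		ATA	TAA
cob	+	2272	3408		ATG	TAA
trnS2	+	3407	3476	TCA
nad1	-	3564	4433		ATA	TAG
trnL1	-	4455	4521	CTA
rrnL	-	4499	5866
trnV	-	5858	5921	GTA
rrnS	-	5920	6737
CR	+	6738	7986
trnI	+	7987	8053	ATC
trnQ	-	8060	8127	CAA
trnM	+	8129	8195	ATG
nad2	+	8223	9204		ATG	TAA
trnW	+	9219	9284	TGA
trnC	-	9288	9352	TGC
trnY	-	9354	9418	TAC
cox1	+	9420	10931		ATA	TAA
cox2	+	11013	11699		ATG	TAA
trnL2	+	11756	11821	TTA
trnK	+	11981	12048	AAA
trnD	+	12050	12112	GAC
atp8	+	12113	12277		ATG	TAA
atp6	+	12271	12936		ATG	TAA
cox3	+	12951	13733		ATA	TAA
trnG	+	13740	13806	GGA
nad3	+	13807	14172		ATG	TAA
trnA	+	14159	14221	GCA
trnR	+	14222	14285	CGA
trnN	+	14285	14349	AAC
trnS1	+	14350	14417	AGA
trnE	+	14418	14486	GAA
trnF	-	14487	14550	TTC
nad5	-	14558	16261		ATG	TAA
trnH	-	16280	16343	CAC
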