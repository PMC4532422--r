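# Gene-region annotation of the human mitochondrial genome (rCRS, NC_012920).
# Partition convention: the rows tile positions 1..16569 with no overlap.
# Feature boundaries follow the standard NC_012920 annotation; intergenic
# spacers are assigned to the upstream feature, and where two genes overlap
# (tRNA-Ile/Gln, tRNA-Cys/Tyr, ATP8/ATP6, ATP6/CO3, ND4L/ND4) the upstream
# gene owns the shared bases.  Protein rows additionally carry the true coding
# span (cds_start/cds_end) used for codon translation, so a trimmed row start
# never shifts the reading frame; incomplete stop codons are completed by
# polyadenylation and are padded with A during translation.  strand is the
# coding strand (- = light strand).  The control region wraps the origin
# (start > end).
name	start	end	region_class	strand	cds_start	cds_end
MT-CR	16024	576	control	+	NA	NA
MT-TF	577	647	tRNA	+	NA	NA
MT-RNR1	648	1601	rRNA	+	NA	NA
MT-TV	1602	1670	tRNA	+	NA	NA
MT-RNR2	1671	3229	rRNA	+	NA	NA
MT-TL1	3230	3306	tRNA	+	NA	NA
MT-ND1	3307	4262	protein	+	3307	4262
MT-TI	4263	4331	tRNA	+	NA	NA
MT-TQ	4332	4401	tRNA	-	NA	NA
MT-TM	4402	4469	tRNA	+	NA	NA
MT-ND2	4470	5511	protein	+	4470	5511
MT-TW	5512	5586	tRNA	+	NA	NA
MT-TA	5587	5656	tRNA	-	NA	NA
MT-TN	5657	5729	tRNA	-	NA	NA
MT-OLR	5730	5760	control	+	NA	NA
MT-TC	5761	5826	tRNA	-	NA	NA
MT-TY	5827	5903	tRNA	-	NA	NA
MT-CO1	5904	7445	protein	+	5904	7445
MT-TS1	7446	7517	tRNA	-	NA	NA
MT-TD	7518	7585	tRNA	+	NA	NA
MT-CO2	7586	8294	protein	+	7586	8269
MT-TK	8295	8365	tRNA	+	NA	NA
MT-ATP8	8366	8572	protein	+	8366	8572
MT-ATP6	8573	9207	protein	+	8527	9207
MT-CO3	9208	9990	protein	+	9207	9990
MT-TG	9991	10058	tRNA	+	NA	NA
MT-ND3	10059	10404	protein	+	10059	10404
MT-TR	10405	10469	tRNA	+	NA	NA
MT-ND4L	10470	10766	protein	+	10470	10766
MT-ND4	10767	12137	protein	+	10760	12137
MT-TH	12138	12206	tRNA	+	NA	NA
MT-TS2	12207	12265	tRNA	+	NA	NA
MT-TL2	12266	12336	tRNA	+	NA	NA
MT-ND5	12337	14148	protein	+	12337	14148
MT-ND6	14149	14673	protein	-	14149	14673
MT-TE	14674	14746	tRNA	-	NA	NA
MT-CYB	14747	15887	protein	+	14747	15887
MT-TT	15888	15955	tRNA	+	NA	NA
MT-TP	15956	16023	tRNA	-	NA	NA
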