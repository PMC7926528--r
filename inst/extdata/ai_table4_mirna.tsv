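mirna	overlap_genes	n_targets	k_overlap	p_value
hsa-miR-3195	MSX2, VDR	23	2	0.00287231
hsa-miR-382-5p	DLX3, SLC10A7, NHS, RUNX1	186	4	0.003965
hsa-miR-1306-5p	SLC4A1, CNNM4, SLC10A7, CLDN16	199	4	0.00503641
hsa-miR-4683	SLC24A4, ENPP1, STIM1	108	3	0.00629218
hsa-miR-6716-3p	ENPP1	4	1	0.01385705
hsa-miR-3914	SLC24A4, CNNM4	56	2	0.01624945
hsa-miR-3935	PHEX, SLC10A7	56	2	0.01624945
hsa-miR-23a-5p	SLC4A4, GJA1, CLDN16	155	3	0.0167345
hsa-miR-4509	SLC24A4, ORAI1	57	2	0.01680318
hsa-miR-1244	GALNT3, SLC4A1	59	2	0.01793454
hsa-miR-939-3p	KLK4, RUNX1, SLC4A4, SLC24A4, CLDN16	439	5	0.01799166
hsa-miR-3938	ENPP1, CACNA1C	65	2	0.02151565
hsa-miR-802	PHEX, SLC4A1	68	2	0.0234085
hsa-miR-615-5p	MSX2, VDR	70	2	0.02470722
hsa-miR-4760-3p	DSPP, NHS	71	2	0.02536746
hsa-miR-221-3p	GALNT3, GJA1, PEX1, RUNX1, SLC10A7	489	5	0.02716289
hsa-miR-1297	GALNT3, CACNA1C, SLC4A4, SLC24A4, NHS	496	5	0.02864777
hsa-miR-6895-5p	GALNS, CNNM4	83	2	0.03383429
hsa-miR-1249-3p	LTBP3	10	1	0.03428995
hsa-miR-3686	GALNT3, MSX2	84	2	0.03458354
hsa-miR-187-5p	GALNT3, SLC10A7	84	2	0.03458354
hsa-miR-222-3p	GALNT3, PCNT, GJA1, RUNX2, SLC10A7	523	5	0.03485762
hsa-miR-937-3p	PEX6	11	1	0.03765479
hsa-miR-217	SLC4A4, RUNX2, RUNX1	219	3	0.04067934
hsa-miR-7111-3p	SLC4A1, CNNM4, RUNX1	219	3	0.04067934
hsa-miR-495-5p	NHS, SLC10A7	92	2	0.04080612
hsa-miR-6749-5p	VDR	12	1	0.04100813
hsa-miR-5189-3p	GALNS, SLC10A7	94	2	0.04242339
hsa-miR-8087	GALNT3, ORAI1	94	2	0.04242339
hsa-miR-4799-5p	ORAI1, SLC10A7	94	2	0.04242339
hsa-miR-20b-3p	GALNT3, SLC24A4	95	2	0.04324099
hsa-miR-6852-5p	SLC4A4, KLK4, CLDN16	228	3	0.04494714
hsa-miR-4446-5p	ARHGAP6, RUNX1, VDR	231	3	0.04641776
hsa-miR-548u	ORAI1, NHS	101	2	0.04826897
hsa-miR-758-3p	CNNM4, CLDN19	102	2	0.04912692
hsa-miR-7161-5p	ORAI1, NHS	103	2	0.04999043
hsa-miR-548v	GALNT3, SLC10A7	103	2	0.04999043
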