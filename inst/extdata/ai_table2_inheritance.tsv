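category	genes
autosomal_recessive	ACP4, AIRE, ALPL, AMBN, CLDN16, CLDN19, CNNM4, CYP27B1, DMP1, ENPP1, FAM20A, FAM20C, GALNS, GALNT3, GPR68, ITGB4, ITGB6, KCNJ1, KLK4, LAMA3, LAMB3, LTBP3, MMP20, ODAPH, ORAI1, PCNT, PEX1, PEX6, PEX26, RELT, ROGDI, SLC4A1, SLC4A4, SLC10A7, SLC13A5, SLC24A4, STIM1, TP63, VDR, WDR72
autosomal_dominant	ALPL, AMBN, AMTN, CACNA1C, CNNM4, COL17A1, DLX3, DSPP, ENAM, FAM83H, GJA1, LAMA3, LAMB3, MSX2, RUNX2, SLC4A1
x_linked_recessive	ARHGAP6
x_linked_dominant	AMELX, GLA, NHS, PHEX
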