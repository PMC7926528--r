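category	genes
isolated	ACP4, AMBN, AMELX, AMTN, ARHGAP6, DLX3, ENAM, FAM83H, GPR68, ITGB6, KLK4, LAMA3, LAMB3, MMP20, ODAPH, SLC24A4, WDR72
syndromic	AIRE, ALPL, AMELX, CACNA1C, CLDN16, CLDN19, CNNM4, COL17A1, CYP27B1, DLX3, DMP1, DSPP, ENPP1, FMA20A, FAM20C, GALNS, GALNT3, GJA1, GLA, ITGB4, KCNJ1, LAMA3, LAMB3, LTBP3, MSX2, NHS, ORAI1, PCNT, PEX1, PEX6, PEX26, PHEX, RELT, ROGDI, RUNX1, RUNX2, SLC4A1, SLC4A4, SLC10A7, SLC13A5, STIM1, TP63, VDR, WDR72
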