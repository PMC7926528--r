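category	genes
hypoplastic	ACP4, AIRA, ALPL, AMBN, AMELX, CLDN16, CLDN19, CNNM4, COL17A1, CYP27B1, DLX3, DSPP, ENPP1, ENAM, FAM20A, FAM20C, GALNT3, GJA1, GLA, ITGB4, ITGB6, KCNJ1, LAMA3, LAMB3, LTBP3, MMP20, ODAPH, PEX1, PEX6, PEX26, PHEX, ROGDI, RUNX1, RUNX2, SLC4A4, SLC10A7, SLC13A5, TP63, VDR, WDR72
hypomaturation	AMELX, CLDN16, CLDN19, CNNM4, KLK4, MMP20, MSX2, ROGDI, RUNX2, SLC24A4, STIM1, TP63, WDR72
hypocalcified	AMBN, AMELX, AMTN, CNNM4, DMP1, DSPP, ENAM, FAM83H, GPR68, ITGB6, KLK4, MMP20, ODAPH, ORAI1, PEX1, RELT, ROGDI, SLC10A7, SLC24A4, STIM1, TP63, WDR72
taurodontism_type	ALPL, DLX3, LAMB3
unspecified	ARHGAP6, CACNA1C, GALNS, NHS, PCTN, SLC4A1
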