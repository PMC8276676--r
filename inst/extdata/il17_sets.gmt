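IL-17 signaling pathway	KEGG-like fixture	ANAPC5	CCL2	CCL20	CCL7	CXCL1	CXCL10	CXCL2	CXCL3	CXCL8	DEFB4A	DEFB4B	ELAVL1	FOS	FOSL1	HSP90AA1	IFNG	IKBKE	IKBKG	IL17A	IL17D	IL17F	IL17RA	IL17RE	IL1B	JUN	JUND	LCN2	MAP3K7	MAPK10	MAPK11	MAPK13	MAPK14	MAPK3	MAPK9	MMP1	MMP13	MMP3	MMP9	NFKB1	S100A7	S100A8	S100A9	SRSF1	TAB2	TAB3	TNF	TNFAIP3	TRADD	TRAF2	TRAF3IP2	TRAF6
Ribosome	KEGG-like fixture	RPL10	RPL11	RPL12	RPL13	RPL14	RPL3	RPL4	RPL5	RPL6	RPL7	RPL8	RPL9	RPS10	RPS11	RPS12	RPS13	RPS2	RPS3	RPS4	RPS5	RPS6	RPS7	RPS8	RPS9
Cell cycle	KEGG-like fixture	AURKA	AURKB	BUB1	CCNA2	CCNB1	CCND1	CCNE1	CDC20	CDC25A	CDK1	CDK2	CDK4	CDK6	CHEK1	E2F1	E2F2	MAD2L1	PLK1	RB1	WEE1
p53 signaling pathway	KEGG-like fixture	APAF1	BAX	BBC3	CASP3	CDKN1A	CDKN2A	GADD45A	MDM2	MDM4	PERP	PMAIP1	PUMA	RRM2B	SESN1	SESN2	SFN	SIAH1	TP53	TP53I3	ZMAT3
Oxidative phosphorylation	KEGG-like fixture	ATP5F1A	ATP5F1B	ATP5MC1	COX4	COX5	COX6	COX7	COX8	CYC1	NDUFA1	NDUFA10	NDUFA2	NDUFA3	NDUFA4	NDUFA5	NDUFA6	NDUFA7	NDUFA8	NDUFA9	SDHA	SDHB	UQCRC1	UQCRC2
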