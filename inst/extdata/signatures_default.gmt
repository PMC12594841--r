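naiveness	NA	LEF1	TCF7	SELL	CCR7
cytotoxicity	NA	GNLY	GZMB	PRF1
exhaustion	NA	HAVCR2	TIGIT	PDCD1
teff_murine	NA	Ccl3	Cx3cr1	Gzma	Gzmb	Klra3	Klrg1	Prdm1	S1pr5
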