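chr17	27699999	27780000	TAOK1	0	+
chr17	27999999	28300000	SSH2	0	+
chr17	28939999	29010000	NF1REPa	0	+
chr17	29064504	29103504	SUZ12P	0	+
chr17	29249999	29270000	ADAP2	0	+
chr17	29699999	29860000	RAB11FIP4	0	+
chr17	30178999	30185000	COPRS	0	+
chr17	30199999	30230000	UTP6	0	+
chr17	30263999	30329000	SUZ12	0	+
chr17	30334999	30380000	NF1REPc	0	+
chr17	31339999	32500000	ASIC2	0	+
chr17	34099999	34130000	MMP28	0	+
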