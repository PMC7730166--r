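mouse_symbol	human_symbol
Speer5-ps1	NA
Smad9	SMAD9
Brd3	BRD3
Arl15	ARL15
Sorbs1	SORBS1
Mcc	MCC
Col4a2	COL4A2
Kcnq1	KCNQ1
Dgki	DGKI
Gng4	GNG4
Acadm	ACADM
Rabggtb	RABGGTB
Abi3bp	ABI3BP
Edn3	EDN3
Nxph1	NXPH1
Atxn1	ATXN1
Il10ra	IL10RA
Gm15997	NA
Wdr95	NA
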