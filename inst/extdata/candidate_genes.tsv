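gene	source	name
SMAD9	chipseq_target	SMAD Family Member 9
BRD3	chipseq_target	Bromodomain Containing 3
ARL15	chipseq_target	ADP Ribosylation Factor Like GTPase 15
SORBS1	chipseq_target	Sorbin And SH3 Domain Containing 1
MCC	chipseq_target	MCC Regulator of WNT Signaling Pathway
COL4A2	chipseq_target	Collagen Type IV Alpha 2 Chain
KCNQ1	chipseq_target	Potassium Voltage-Gated Channel Subfamily Q Member 1
DGKI	chipseq_target	Diacylglycerol Kinase Iota
GNG4	chipseq_target	G Protein Subunit Gamma 4
ACADM	chipseq_target	Acyl-CoA Dehydrogenase Medium Chain
RABGGTB	chipseq_target	Rab Geranylgeranyltransferase Subunit Beta
ABI3BP	chipseq_target	ABI Family Member 3 Binding Protein
EDN3	chipseq_target	Endothelin 3
NXPH1	chipseq_target	Neurexophilin 1
ATXN1	chipseq_target	Ataxin 1
IL10RA	chipseq_target	Interleukin 10 Receptor Subunit Alpha
TGFB1	related	Transforming Growth Factor Beta 1
VHL	related	Von Hippel-Lindau Tumor Suppressor
APP	related	Amyloid Beta Precursor Protein
MYC	related	MYC Proto-Oncogene, BHLH Transcription Factor
NTRK1	related	Neurotrophic Receptor Tyrosine Kinase 1
GRB2	related	Neurotrophic Receptor Tyrosine Kinase 1
HRAS	related	Neurotrophic Receptor Tyrosine Kinase 1
HTT	related	Huntingtin
TNF	related	Tumor Necrosis Factor
HIST1H3A	related	Histone Cluster 1 H3 Family
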