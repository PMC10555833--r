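protein1	protein2	source
HDAC2	CHD4	example-complex
HDAC2	RBBP4	example-complex
HDAC2	MTA1	example-complex
CHD4	RBBP4	example-complex
CHD4	MTA1	example-complex
RBBP4	MTA1	example-complex
SIN3A	RBBP4	example-complex
SIN3A	SAP30	example-complex
GNA12	GNB1	example-signaling
AFDN	NECTIN4	example-adhesion
ACTB	ACTN1	example-cytoskeleton
RPL3	RPL4	example-ribosome
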