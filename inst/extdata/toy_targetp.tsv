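accession	prediction	CS
P1	cTP	50
P2	mTP	35
P3	SP	22
P4	noTP
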